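{
  "name": "pvi_like_14slice",
  "slices": [
    {
      "name": "Transmissible Cases",
      "domain": "Infection Rate",
      "weight": 1,
      "color": "#D7191C",
      "components": [
        {
          "name": "transmissible_cases",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Disease Spread",
      "domain": "Infection Rate",
      "weight": 1,
      "color": "#E85B5B",
      "components": [
        {
          "name": "spread_rate",
          "direction": "higher_is_worse",
          "weight": 2
        },
        {
          "name": "reproduction_number",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Population Mobility",
      "domain": "Population Concentration",
      "weight": 1,
      "color": "#FDAE61",
      "components": [
        {
          "name": "daytime_traffic",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Residential Density",
      "domain": "Population Concentration",
      "weight": 1,
      "color": "#FDC980",
      "components": [
        {
          "name": "residential_density",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Daytime Density",
      "domain": "Population Concentration",
      "weight": 1,
      "color": "#FEE0A8",
      "components": [
        {
          "name": "daytime_density",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Social Distancing",
      "domain": "Intervention Measures",
      "weight": 1,
      "color": "#1A9641",
      "components": [
        {
          "name": "distancing_score",
          "direction": "lower_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Testing Rates",
      "domain": "Intervention Measures",
      "weight": 1,
      "color": "#58B66A",
      "components": [
        {
          "name": "tests_per_capita",
          "direction": "lower_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Vaccination Coverage",
      "domain": "Intervention Measures",
      "weight": 1,
      "color": "#96D693",
      "components": [
        {
          "name": "vaccinated_pct",
          "direction": "lower_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Population Demographics",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#2C7BB6",
      "components": [
        {
          "name": "minority_pct",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Air Pollution",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#4D94C4",
      "components": [
        {
          "name": "pm25",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Age Distribution",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#6EADD2",
      "components": [
        {
          "name": "over65_pct",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Comorbidities",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#8FC6E0",
      "components": [
        {
          "name": "comorbidity_index",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Health Disparities",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#B0DFEE",
      "components": [
        {
          "name": "uninsured_pct",
          "direction": "higher_is_worse",
          "weight": 1
        },
        {
          "name": "poverty_pct",
          "direction": "higher_is_worse",
          "weight": 1
        }
      ]
    },
    {
      "name": "Hospital Beds",
      "domain": "Health & Environment",
      "weight": 1,
      "color": "#D1F0FA",
      "components": [
        {
          "name": "beds_per_capita",
          "direction": "lower_is_worse",
          "weight": 1
        }
      ]
    }
  ]
}
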
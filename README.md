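# toxpigis

**GIS-ready ToxPi glyph layers and local hotspot analysis, in open formats.**

Public-health and environmental analyses increasingly need to communicate
*integrated* risk — not just a single score per county or census tract, but
the individual factors driving that score, placed on a map people can
explore. The Toxicological Prioritization Index (ToxPi) framework answers
the first half: heterogeneous indicators are grouped into weighted
"slices" of a radar glyph, each scored on [0, 1], and combined into a
normalized overall score. `toxpigis` answers the second half without any
proprietary GIS software: it draws each record's ToxPi profile as
geolocated wedge polygons in a projected equal-area coordinate system,
assembles the multi-scale layers an interactive map needs, runs Getis-Ord
Gi\* hotspot analysis on the scores, and writes everything as standard
GeoJSON (RFC 7946) plus small JSON styling sidecars.

It is aimed at spatial epidemiologists and exposure scientists who have a
table of county-level (or tract-level) indicators and want shareable,
joinable map layers and defensible hotspot statistics from a single
command.

## The model

For record *r* with components *c* grouped into slices *i*:

- each component column is min–max scaled to [0, 1] over the cohort
  (`lower_is_worse` components are inverted, so larger always means more
  vulnerable);
- slice scores are within-slice weighted means,
  `s_i = Σ_c w_c x_c / Σ_c w_c`;
- the overall score is the weight-normalized combination
  `S = Σ_i w_i s_i / Σ_i w_i ∈ [0, 1]`.

In the glyph, slice *i* occupies an angular sector of width
`360° · w_i / Σ w` (clockwise from north) and radial extent
`s_i · r_max` metres.

Hotspots use the Getis-Ord Gi\* statistic with binary distance-band
weights (great-circle, self included):

```
Gi* = [ Σ_j w_ij x_j − X̄ Σ_j w_ij ] /
      ( S √( [n Σ_j w_ij² − (Σ_j w_ij)²] / (n−1) ) )
```

which is itself a z-score. Two-sided normal p-values (optionally
Benjamini–Hochberg adjusted across records) are classified into seven
confidence bins: ±3 (99 %), ±2 (95 %), ±1 (90 %), 0 (not significant),
sign following the z-score — hot red, cold blue.

## Worked example

Simulate a county-like lattice with a planted high-vulnerability cluster,
score it under the bundled 4-domain / 14-slice vulnerability-style model,
and look for hotspots:

```r
library(toxpigis)

spec <- sim_spec(n_cols = 6, n_rows = 6, n_groups = 2,
                 clusters = list(list(col = 3, row = 3,
                                      radius_km = 60, delta = 3)),
                 seed = 42)
sim    <- generate_lattice(spec)
scores <- toxpi_score(sim$data, sim$model)
head(scores[, c("record_id", "overall", "Transmissible Cases")], 4)
#>   record_id   overall Transmissible Cases
#> 1      c001 0.2552748          0.22918822
#> 2      c002 0.2654361          0.23479159
#> 3      c003 0.2256616          0.07100439
#> 4      c004 0.1939144          0.20796212

hs <- hotspot_analysis(scores, field = "overall", band_miles = 30)
table(bin = hs$bin)
#> bin
#>  0  1  2  3
#> 31  1  2  2
subset(hs, bin == 3)[, c("record_id", "value", "gi_z", "p_adj", "bin")]
#>    record_id     value     gi_z        p_adj bin
#> 15      c015 0.8065498 5.199984 7.175002e-06   3
#> 16      c016 0.8799190 3.564011 6.574152e-03   3
```

The overall scores sit in [0, 1]; records `c015`/`c016` — inside the
planted cluster — are flagged as 99 %-confidence hotspots (bin +3) after
FDR adjustment, while the background stays at bin 0.

To produce the full map product (local glyphs, density-reduced glyphs,
group-median glyphs, two choropleths, maximum-radius rings, with styling
sidecars):

```r
write_simulation(sim, "fixture/")
run_toolkit("fixture/data.csv", "layers/")
```

or, from a shell, via the bundled CLI (`inst/cli/toxpigis`):

```sh
toxpigis simulate -o fixture --seed 42 --n-cols 6 --n-rows 6 --delta 3
toxpigis run-all  -i fixture/data.csv -o layers
toxpigis hotspot  -i fixture/data.csv -o hotspots --band-miles 50
```

`run-all` needs only the input file and the output directory; a model
JSON, group labels and boundary polygons are picked up automatically when
they sit next to the input (as `write_simulation()`/`simulate` arrange).

## Package layout

- `R/model.R`, `R/scoring.R` — model configuration and the scoring chain
- `R/crs.R`, `R/glyph.R` — equal-area projection and wedge/ring geometry
- `R/layers.R`, `R/geojson.R` — feature layers, GeoJSON and sidecars
- `R/hotspot.R` — spatial weights, Gi\*, FDR, seven-bin classification
- `R/simulate.R` — synthetic lattice fixtures and the bundled model
- `R/pipeline.R`, `R/cli.R` — one-shot pipeline and CLI subcommands
- `vignettes/toxpigis-methods.Rmd` — methods, assumptions and limitations
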
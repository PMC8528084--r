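# --- synthetic county-lattice fixtures -------------------------------------

#' A 4-domain / 14-slice pandemic-vulnerability-style ToxPi model
#'
#' Mirrors the structure of county-level pandemic vulnerability models:
#' four domains (infection rate, population concentration, intervention
#' measures, health and environment) split into 14 slices.  Slice weights
#' are documented placeholders (all 1); substitute real weights via a model
#' JSON file for production analyses.  Protective factors (social
#' distancing, testing, vaccination, hospital beds) are `lower_is_worse` so
#' their scaled contributions are inverted.
#'
#' @return A [toxpi_model()] with 14 slices in 4 domains and 16 components.
#' @examples
#' m <- pvi_like_model()
#' length(m$slices)   # 14
#' length(m$domains)  # 4
#' @export
pvi_like_model <- function() {
  hw <- "higher_is_worse"; lw <- "lower_is_worse"
  sl <- function(name, domain, color, comps) {
    toxpi_slice(name, comps, weight = 1, domain = domain, color = color)
  }
  toxpi_model("pvi_like_14slice", list(
    sl("Transmissible Cases", "Infection Rate", "#D7191C",
       list(toxpi_component("transmissible_cases", hw))),
    sl("Disease Spread", "Infection Rate", "#E85B5B",
       list(toxpi_component("spread_rate", hw, weight = 2),
            toxpi_component("reproduction_number", hw, weight = 1))),
    sl("Population Mobility", "Population Concentration", "#FDAE61",
       list(toxpi_component("daytime_traffic", hw))),
    sl("Residential Density", "Population Concentration", "#FDC980",
       list(toxpi_component("residential_density", hw))),
    sl("Daytime Density", "Population Concentration", "#FEE0A8",
       list(toxpi_component("daytime_density", hw))),
    sl("Social Distancing", "Intervention Measures", "#1A9641",
       list(toxpi_component("distancing_score", lw))),
    sl("Testing Rates", "Intervention Measures", "#58B66A",
       list(toxpi_component("tests_per_capita", lw))),
    sl("Vaccination Coverage", "Intervention Measures", "#96D693",
       list(toxpi_component("vaccinated_pct", lw))),
    sl("Population Demographics", "Health & Environment", "#2C7BB6",
       list(toxpi_component("minority_pct", hw))),
    sl("Air Pollution", "Health & Environment", "#4D94C4",
       list(toxpi_component("pm25", hw))),
    sl("Age Distribution", "Health & Environment", "#6EADD2",
       list(toxpi_component("over65_pct", hw))),
    sl("Comorbidities", "Health & Environment", "#8FC6E0",
       list(toxpi_component("comorbidity_index", hw))),
    sl("Health Disparities", "Health & Environment", "#B0DFEE",
       list(toxpi_component("uninsured_pct", hw),
            toxpi_component("poverty_pct", hw))),
    sl("Hospital Beds", "Health & Environment", "#D1F0FA",
       list(toxpi_component("beds_per_capita", lw)))
  ))
}

#' Specification for a synthetic county lattice
#'
#' Describes a regular `n_cols x n_rows` point lattice with square boundary
#' cells, i.i.d. Uniform(0, 1) baseline noise per component, optional
#' planted high-score spatial clusters, and `n_groups` vertical bands of
#' columns acting as synthetic states.
#'
#' @param n_cols,n_rows Lattice dimensions.
#' @param origin_lat,origin_lon WGS84 position of the south-west lattice
#'   point (defaults place the lattice in the central United States).
#' @param spacing_km Point spacing in kilometres (default 30, a typical
#'   county-centroid spacing).
#' @param clusters List of planted clusters, each
#'   `list(col, row, radius_km, delta)`: records within `radius_km`
#'   (great-circle) of the centre point get `delta` added to every
#'   `higher_is_worse` component before scaling.
#' @param n_groups Number of vertical "state" bands.
#' @param seed Integer RNG seed (required; the generator is deterministic
#'   given the spec).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_cols = 12, n_rows = 12, origin_lat = 36,
                     origin_lon = -98, spacing_km = 30,
                     clusters = list(), n_groups = 4, seed = 1) {
  if (n_cols < 1 || n_rows < 1) {
    stop("lattice must have at least one column and one row", call. = FALSE)
  }
  if (spacing_km <= 0) stop("spacing_km must be positive", call. = FALSE)
  for (cl in clusters) {
    stopifnot(!is.null(cl$col), !is.null(cl$row), !is.null(cl$radius_km),
              !is.null(cl$delta))
    if (cl$delta < 0) stop("cluster delta must be >= 0", call. = FALSE)
    if (cl$col < 1 || cl$col > n_cols || cl$row < 1 || cl$row > n_rows) {
      stop("cluster centre outside the lattice", call. = FALSE)
    }
  }
  if (is.null(seed)) stop("seed must be set", call. = FALSE)
  structure(list(n_cols = n_cols, n_rows = n_rows, origin_lat = origin_lat,
                 origin_lon = origin_lon, spacing_km = spacing_km,
                 clusters = clusters, n_groups = n_groups,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# degree steps equivalent to spacing_km at the lattice origin
lattice_steps <- function(spec) {
  list(dlat = spec$spacing_km / 110.574,
       dlon = spec$spacing_km /
         (111.320 * cos(spec$origin_lat * pi / 180)))
}

# contiguous vertical bands: first (n_cols %% k) bands get one extra column
lattice_groups <- function(n_cols, n_rows, n_groups) {
  base <- n_cols %/% n_groups
  extra <- n_cols %% n_groups
  cols_per <- rep(base, n_groups) + (seq_len(n_groups) <= extra)
  band_of_col <- rep(seq_len(n_groups), times = cols_per)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  sprintf("state_%02d", band_of_col[grid$col])
}

#' Generate a synthetic county lattice
#'
#' Produces `n_cols * n_rows` records on a regular lattice: a
#' [toxpi_data()] matrix with i.i.d. Uniform(0, 1) component values, square
#' boundary polygons centred on each point, and vertical-band group
#' ("state") labels.  Deterministic given the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @param model Model supplying the component columns (default
#'   [pvi_like_model()]).
#' @return A list with elements `data` ([toxpi_data()]), `boundaries`
#'   (named geometry list for [build_choropleth()]), `groups` (named
#'   character vector id -> group label) and `model`.
#' @export
generate_lattice <- function(spec, model = pvi_like_model()) {
  st <- lattice_steps(spec)
  grid <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  ids <- sprintf("c%03d", seq_len(nrow(grid)))
  lat <- spec$origin_lat + (grid$row - 1) * st$dlat
  lon <- spec$origin_lon + (grid$col - 1) * st$dlon
  comp <- component_names(model)
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  vals <- matrix(stats::runif(nrow(grid) * length(comp)),
                 nrow = nrow(grid), dimnames = list(NULL, comp))
  data <- toxpi_data(ids, lat, lon, vals)
  half_lat <- st$dlat / 2; half_lon <- st$dlon / 2
  boundaries <- lapply(seq_along(ids), function(i) {
    ring <- cbind(c(lon[i] - half_lon, lon[i] + half_lon, lon[i] + half_lon,
                    lon[i] - half_lon, lon[i] - half_lon),
                  c(lat[i] - half_lat, lat[i] - half_lat, lat[i] + half_lat,
                    lat[i] + half_lat, lat[i] - half_lat))
    list(type = "Polygon", rings = list(ring), coords = "wgs84")
  })
  names(boundaries) <- ids
  groups <- lattice_groups(spec$n_cols, spec$n_rows, spec$n_groups)
  names(groups) <- ids
  data <- plant_cluster(data, spec, model)
  list(data = data, boundaries = boundaries, groups = groups, model = model)
}

#' Plant high-score spatial clusters into a data matrix
#'
#' For each cluster in the spec, every record within `radius_km`
#' (great-circle, haversine) of the cluster centre gets `delta` added to
#' all of its `higher_is_worse` components, before any scaling — the
#' planted hotspot therefore propagates through the whole scoring chain.
#' With `delta = 0` the matrix is returned unchanged.
#'
#' @param data A [toxpi_data()] matrix.
#' @param spec A [sim_spec()] (only its `clusters` are used).
#' @param model Model supplying component directions.
#' @return The modified `toxpi_data` object.
#' @export
plant_cluster <- function(data, spec, model = pvi_like_model()) {
  if (!length(spec$clusters)) return(data)
  st <- lattice_steps(spec)
  hw_cols <- unlist(lapply(model$slices, function(s) {
    dirs <- vapply(s$components, `[[`, character(1), "direction")
    vapply(s$components, `[[`, character(1), "name")[dirs == "higher_is_worse"]
  }))
  for (cl in spec$clusters) {
    if (cl$delta == 0) next
    ctr_lat <- spec$origin_lat + (cl$row - 1) * st$dlat
    ctr_lon <- spec$origin_lon + (cl$col - 1) * st$dlon
    d <- geosphere::distHaversine(cbind(data$lon, data$lat),
                                  c(ctr_lon, ctr_lat), r = EARTH_RADIUS_M)
    member <- d <= cl$radius_km * 1000
    data$values[member, hw_cols] <- data$values[member, hw_cols] + cl$delta
  }
  data
}

#' Cluster membership of lattice records
#'
#' @param data A [toxpi_data()] matrix.
#' @param spec A [sim_spec()].
#' @return Logical vector: is the record within any planted cluster radius.
#' @export
cluster_members <- function(data, spec) {
  st <- lattice_steps(spec)
  member <- rep(FALSE, length(data$ids))
  for (cl in spec$clusters) {
    ctr_lat <- spec$origin_lat + (cl$row - 1) * st$dlat
    ctr_lon <- spec$origin_lon + (cl$col - 1) * st$dlon
    d <- geosphere::distHaversine(cbind(data$lon, data$lat),
                                  c(ctr_lon, ctr_lat), r = EARTH_RADIUS_M)
    member <- member | d <= cl$radius_km * 1000
  }
  member
}

#' Write a simulated fixture to disk
#'
#' Emits the four files the rest of the toolkit consumes: the component
#' data CSV, the boundary polygons GeoJSON, the model JSON and the group
#' labels CSV.
#'
#' @param sim Output of [generate_lattice()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "data.csv")
  df <- data.frame(id = sim$data$ids, lat = sim$data$lat,
                   lon = sim$data$lon, check.names = FALSE)
  df <- cbind(df, as.data.frame(sim$data$values, row.names = NULL))
  utils::write.csv(df, data_path, row.names = FALSE)
  bnd_path <- file.path(dir, "boundaries.geojson")
  feats <- lapply(names(sim$boundaries), function(id) {
    list(geometry = sim$boundaries[[id]],
         properties = list(record_id = id,
                           group = unname(sim$groups[id])))
  })
  write_geojson(feature_layer("local_choropleth", feats), bnd_path)
  model_path <- file.path(dir, "model.json")
  write_toxpi_model(sim$model, model_path)
  groups_path <- file.path(dir, "groups.csv")
  utils::write.csv(data.frame(id = names(sim$groups),
                              group = unname(sim$groups)),
                   groups_path, row.names = FALSE)
  c(data = data_path, boundaries = bnd_path, model = model_path,
    groups = groups_path)
}
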
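#' One-shot map-product pipeline
#'
#' Reproduces the "two required parameters" workflow: given an input
#' component CSV and an output directory, scores the records, draws the
#' glyph layers and writes every map product as GeoJSON plus a styling
#' sidecar.  Sibling files of the input are auto-discovered by convention
#' (`model.json`, `groups.csv`, `boundaries.geojson` in the input's
#' directory), so a directory produced by [write_simulation()] runs
#' end-to-end with no further configuration:
#'
#' * `local_glyphs.geojson` — one wedge per record and slice
#' * `local_glyphs_dense.geojson` — same, radius shrunk for dense areas
#' * `group_glyphs.geojson` — group-median glyphs at group centroids
#' * `local_choropleth.geojson` — boundary polygons classed by score
#' * `group_choropleth.geojson` — group outlines classed by median score
#' * `rings.geojson` — maximum-radius rings
#'
#' Group layers need group labels; choropleths need boundary polygons.
#' Layers whose inputs are absent are skipped with a message.
#'
#' @param input Path to the component data CSV (see [read_data_csv()]).
#' @param output Output directory (created if needed).
#' @param model A [toxpi_model()], a model JSON path, or `NULL` to
#'   auto-discover `model.json` (falling back to [pvi_like_model()]).
#' @param groups Named character vector (id -> group), a groups CSV path,
#'   or `NULL` to auto-discover `groups.csv`.
#' @param boundaries Named geometry list, a boundaries GeoJSON path, or
#'   `NULL` to auto-discover `boundaries.geojson`.
#' @param id_col,lat_col,lon_col Column mapping for the input CSV.
#' @param radius_max Local glyph radius in metres.
#' @param group_radius_max Group glyph radius in metres.
#' @param shrink Dense-layer radius factor in (0, 1).
#' @param epsg Projected CRS EPSG code (default 5070).
#' @param k Choropleth class count.
#' @param prescored Treat the input as pre-scored results
#'   (see [read_prescored_csv()]) instead of raw components.
#' @return Invisibly, a list with the `scores` data frame and the named
#'   vector of `files` written.
#' @export
run_toolkit <- function(input, output, model = NULL, groups = NULL,
                        boundaries = NULL, id_col = "id", lat_col = "lat",
                        lon_col = "lon", radius_max = 10000,
                        group_radius_max = 30000, shrink = 0.5, epsg = 5070,
                        k = 5, prescored = FALSE) {
  if (!file.exists(input)) stop("input file not found: ", input, call. = FALSE)
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  in_dir <- dirname(input)
  sibling <- function(name) {
    p <- file.path(in_dir, name)
    if (file.exists(p)) p else NULL
  }
  if (is.null(model)) model <- sibling("model.json")
  if (is.character(model)) model <- read_toxpi_model(model)
  if (is.null(model)) model <- pvi_like_model()
  if (is.null(groups)) groups <- sibling("groups.csv")
  if (is.character(groups)) {
    gdf <- utils::read.csv(groups, stringsAsFactors = FALSE)
    g <- as.character(gdf[[2]]); names(g) <- as.character(gdf[[1]])
    groups <- g
  }
  if (is.null(boundaries)) boundaries <- sibling("boundaries.geojson")
  if (is.character(boundaries)) boundaries <- read_boundaries(boundaries)

  crs <- crs_lookup(epsg)
  spec <- glyph_spec(radius_max = radius_max)
  if (prescored) {
    scores <- read_prescored_csv(input, model, id_col = id_col,
                                 lat_col = lat_col, lon_col = lon_col)
    data <- NULL
  } else {
    data <- read_data_csv(input, id_col = id_col, lat_col = lat_col,
                          lon_col = lon_col)
    scores <- toxpi_score(data, model)
  }

  files <- c()
  emit <- function(layer, stem) {
    gj <- file.path(output, paste0(stem, ".geojson"))
    write_geojson(layer, gj)
    write_layer_sidecar(layer, file.path(output,
                                         paste0(stem, ".style.json")))
    files[[stem]] <<- gj
  }

  local_layer <- build_local_glyph_layer(scores, spec, crs, data = data)
  emit(attach_scale_hints(local_layer, 8, 12), "local_glyphs")
  dense <- build_dense_layer(scores, spec, crs, data = data, shrink = shrink)
  emit(attach_scale_hints(dense, 12, 20), "local_glyphs_dense")
  emit(build_rings_layer(scores, spec, crs), "rings")

  group_scores <- NULL
  if (!is.null(groups)) {
    group_scores <- aggregate_group_medians(scores, groups)
    gl <- build_group_glyph_layer(
      group_scores, glyph_spec(radius_max = group_radius_max), crs)
    emit(attach_scale_hints(gl, 0, 6), "group_glyphs")
  } else {
    message("no group labels found; skipping group layers")
  }

  if (!is.null(boundaries)) {
    emit(build_choropleth(scores, boundaries, k = k), "local_choropleth")
    if (!is.null(group_scores)) {
      hulls <- group_boundary_hulls(boundaries, groups)
      emit(build_choropleth(group_scores, hulls, k = min(k,
                              max(2, nrow(group_scores))),
                            role = "group_choropleth"), "group_choropleth")
    }
  } else {
    message("no boundary polygons found; skipping choropleth layers")
  }

  scores_path <- file.path(output, "scores.csv")
  write_scores_csv(scores, scores_path)
  files[["scores"]] <- scores_path
  invisible(list(scores = scores, files = unlist(files)))
}
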
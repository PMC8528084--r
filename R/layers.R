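layer_roles <- c("local_glyph", "local_glyph_dense", "group_glyph",
                 "local_choropleth", "group_choropleth", "rings", "hotspot")

#' Construct a feature layer
#'
#' A feature layer is a typed collection of geographic features (geometry
#' plus attributes) destined for one map layer, together with advisory
#' rendering metadata (role, zoom-range scale hints, choropleth legend).
#'
#' @param role One of `r paste0('"', layer_roles, '"', collapse = ", ")`.
#' @param features List of features; each feature is a list with `geometry`
#'   (list with `type`, `rings` — a list of coordinate matrices — and
#'   `coords`, either `"projected"` or `"wgs84"`) and `properties` (named
#'   list of attributes).
#' @param crs The `toxpigis_crs` used for projected geometry (may be `NULL`
#'   for layers already in WGS84).
#' @param scale_hint Advisory `c(min_zoom, max_zoom)` pair or `NULL`.
#' @param legend Optional legend data frame (choropleth class breaks).
#' @return An object of class `feature_layer`.
#' @export
feature_layer <- function(role, features, crs = NULL, scale_hint = NULL,
                          legend = NULL) {
  role <- match.arg(role, layer_roles)
  structure(list(role = role, features = features, crs = crs,
                 scale_hint = scale_hint, legend = legend),
            class = "feature_layer")
}

#' @export
print.feature_layer <- function(x, ...) {
  cat("Feature layer [", x$role, "]: ", length(x$features), " features\n",
      sep = "")
  if (!is.null(x$scale_hint)) {
    cat("  scale hint: zoom ", x$scale_hint[1], "-", x$scale_hint[2], "\n",
        sep = "")
  }
  invisible(x)
}

polygon_feature <- function(ring, properties, coords = "projected") {
  list(geometry = list(type = "Polygon", rings = list(ring),
                       coords = coords),
       properties = properties)
}

# raw component values for one record restricted to one slice, for popups
slice_popup_values <- function(data, record_id, slice) {
  if (is.null(data)) return(list())
  cols <- vapply(slice$components, `[[`, character(1), "name")
  vals <- as.list(data$values[record_id, cols, drop = TRUE])
  names(vals) <- cols
  vals
}

#' Build the local ToxPi glyph layer
#'
#' One wedge polygon per record and slice, drawn at the record's projected
#' location.  Wedge attributes carry everything an interactive popup needs:
#' record id, slice, domain, slice score, weight fraction, colour, overall
#' score and (when `data` is supplied) the raw component values behind the
#' slice.
#'
#' @param scores A `toxpi_scores` data frame from [toxpi_score()] /
#'   [toxpi_scores()].
#' @param spec A [glyph_spec()].
#' @param crs Projected CRS (see [crs_lookup()]).
#' @param data Optional [toxpi_data()] with the raw component values.
#' @param slices Optional slice subset to draw.
#' @param role Layer role; used internally by [build_dense_layer()].
#' @return A `feature_layer` with `nrow(scores) * n_slices` features.
#' @export
build_local_glyph_layer <- function(scores, spec = glyph_spec(),
                                    crs = crs_lookup(5070), data = NULL,
                                    slices = NULL, role = "local_glyph") {
  model <- attr(scores, "model")
  if (anyDuplicated(scores$record_id)) {
    stop("duplicate record id(s) in scores", call. = FALSE)
  }
  ctr <- project_points(scores$lat, scores$lon, crs)
  ss <- score_matrix(scores)
  grp <- if ("group" %in% names(scores)) scores$group else scores$record_id
  features <- list()
  for (i in seq_len(nrow(scores))) {
    wedges <- build_glyph(ss[i, ], model, ctr$x[i], ctr$y[i], spec,
                          slices = slices)
    for (wd in wedges) {
      sl <- model$slices[[match(wd$slice, slice_names(model))]]
      props <- c(list(record_id = scores$record_id[i],
                      group = grp[i],
                      slice = wd$slice, domain = wd$domain,
                      slice_score = wd$score,
                      weight_fraction = wd$weight_fraction,
                      color = wd$color,
                      overall = scores$overall[i]),
                 slice_popup_values(data, scores$record_id[i], sl))
      features[[length(features) + 1L]] <- polygon_feature(wd$ring, props)
    }
  }
  feature_layer(role, features, crs = crs)
}

#' Build the density-reduced glyph layer
#'
#' Identical to the local glyph layer but with every glyph radius shrunk by
#' a fixed factor, so glyphs remain separable in dense areas when zoomed in.
#'
#' @inheritParams build_local_glyph_layer
#' @param shrink Radius shrink factor, strictly between 0 and 1.
#' @return A `feature_layer` with role `local_glyph_dense`; the same
#'   feature count and attribute table as the local layer, only the
#'   geometry differs.
#' @export
build_dense_layer <- function(scores, spec = glyph_spec(),
                              crs = crs_lookup(5070), data = NULL,
                              slices = NULL, shrink = 0.5) {
  if (!is.numeric(shrink) || length(shrink) != 1L || shrink <= 0 ||
      shrink >= 1) {
    stop("shrink must lie strictly between 0 and 1", call. = FALSE)
  }
  spec2 <- spec
  spec2$radius_max <- spec$radius_max * shrink
  build_local_glyph_layer(scores, spec2, crs, data, slices,
                          role = "local_glyph_dense")
}

#' Build the maximum-radius rings layer
#'
#' One circle of radius `spec$radius_max` per record, marking each glyph's
#' full extent.
#'
#' @inheritParams build_local_glyph_layer
#' @return A `feature_layer` with role `rings` and one feature per record.
#' @export
build_rings_layer <- function(scores, spec = glyph_spec(),
                              crs = crs_lookup(5070)) {
  ctr <- project_points(scores$lat, scores$lon, crs)
  features <- lapply(seq_len(nrow(scores)), function(i) {
    ring <- build_ring(ctr$x[i], ctr$y[i], spec$radius_max, spec$arc_step)
    polygon_feature(ring, list(record_id = scores$record_id[i],
                               overall = scores$overall[i]))
  })
  feature_layer("rings", features, crs = crs)
}

#' Build the group-median glyph layer
#'
#' One ToxPi glyph per group, drawn from the per-slice group medians at the
#' group centroid (mean of member projected points, or coordinates already
#' present on the aggregated scores).  The default radius is larger than
#' the local layer's so group glyphs read well when zoomed out.
#'
#' @param group_scores Output of [aggregate_group_medians()].
#' @param spec A [glyph_spec()]; defaults to a 3x larger radius.
#' @param crs Projected CRS.
#' @return A `feature_layer` with role `group_glyph` and
#'   `n_groups * n_slices` features; every feature carries its group label.
#' @export
build_group_glyph_layer <- function(group_scores,
                                    spec = glyph_spec(radius_max = 60000),
                                    crs = crs_lookup(5070)) {
  if (any(!is.finite(group_scores$lat)) || any(!is.finite(group_scores$lon))) {
    stop("missing centroid coordinates for group(s): ",
         paste(group_scores$record_id[!is.finite(group_scores$lat) |
                                        !is.finite(group_scores$lon)],
               collapse = ", "), call. = FALSE)
  }
  build_local_glyph_layer(group_scores, spec, crs, role = "group_glyph")
}

#' Quantile class breaks for a choropleth
#'
#' @param values Numeric vector of scores.
#' @param k Number of classes (default 5).
#' @param palette Function `n -> n colours` (default a yellow-to-red ramp).
#' @return Data frame with columns `lower`, `upper`, `color`, `label`;
#'   classes are contiguous, non-overlapping and cover the observed range.
#'   Duplicate quantiles collapse the class count with a warning.
#' @export
choropleth_classes <- function(values, k = 5, palette = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (is.null(palette)) {
    palette <- grDevices::colorRampPalette(c("#FFFFB2", "#FD8D3C", "#BD0026"))
  }
  values <- values[is.finite(values)]
  br <- unique(stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                               names = FALSE))
  if (length(br) < 2L) {  # all values identical
    warning("all scores equal; choropleth collapses to a single class")
    br <- c(br, br)
  } else if (length(br) < k + 1L) {
    warning("duplicate quantile breaks; choropleth reduced to ",
            length(br) - 1L, " classes")
  }
  nclass <- length(br) - 1L
  data.frame(lower = br[-length(br)], upper = br[-1],
             color = palette(nclass),
             label = sprintf("%.3f - %.3f", br[-length(br)], br[-1]),
             stringsAsFactors = FALSE)
}

# class index of each value given a legend (right-closed; first class
# includes its lower bound)
classify_values <- function(values, legend) {
  idx <- findInterval(values, c(legend$lower[1], legend$upper),
                      all.inside = TRUE)
  idx
}

#' Build a choropleth layer from boundary polygons
#'
#' Attributes each boundary polygon with its record's overall score and
#' quantile class, producing a classed score map.
#'
#' @param scores A `toxpi_scores` data frame (records or groups).
#' @param boundaries Named list of boundary geometries keyed by record id /
#'   group label; each element a geometry list as read by [read_geojson()]
#'   (WGS84 rings).  Records without a boundary are skipped with a warning.
#' @param k Number of quantile classes.
#' @param value Score column to map (default `"overall"`).
#' @param role `"local_choropleth"` or `"group_choropleth"`.
#' @param palette Optional colour-ramp function.
#' @return A `feature_layer` with one feature per matched record and a
#'   `legend` describing the class breaks.
#' @export
build_choropleth <- function(scores, boundaries, k = 5, value = "overall",
                             role = "local_choropleth", palette = NULL) {
  role <- match.arg(role, c("local_choropleth", "group_choropleth"))
  if (!value %in% names(scores)) {
    stop("unknown score field: ", value, call. = FALSE)
  }
  ids <- scores$record_id
  have <- ids %in% names(boundaries)
  if (any(!have)) {
    warning("no boundary polygon for ", sum(!have), " record(s): ",
            paste(utils::head(ids[!have], 5), collapse = ", "),
            "; skipped")
  }
  vals <- scores[[value]]
  legend <- choropleth_classes(vals[have], k = k, palette = palette)
  cls <- classify_values(vals, legend)
  features <- list()
  for (i in which(have)) {
    geom <- boundaries[[ids[i]]]
    geom$coords <- "wgs84"
    features[[length(features) + 1L]] <- list(
      geometry = geom,
      properties = list(record_id = ids[i], score = vals[i],
                        class = cls[i],
                        color = legend$color[cls[i]],
                        class_label = legend$label[cls[i]]))
  }
  feature_layer(role, features, crs = NULL, legend = legend)
}

#' Attach advisory zoom-range scale hints to a layer
#'
#' Scale hints are renderer metadata only (serialized to the layer's
#' sidecar); the geometry is untouched.  Convention: group layers carry
#' small zoom ranges (visible zoomed out), local and dense layers larger
#' ones (visible zoomed in).
#'
#' @param layer A `feature_layer`.
#' @param min_zoom,max_zoom Advisory web-map zoom levels,
#'   `min_zoom <= max_zoom`.
#' @return The layer with its `scale_hint` set.
#' @export
attach_scale_hints <- function(layer, min_zoom, max_zoom) {
  if (min_zoom > max_zoom) {
    stop("min_zoom must not exceed max_zoom", call. = FALSE)
  }
  layer$scale_hint <- c(min_zoom = min_zoom, max_zoom = max_zoom)
  layer
}

# default zoom ranges per role
default_scale_hint <- function(role) {
  switch(role,
         group_glyph = c(0, 6), group_choropleth = c(0, 6),
         local_choropleth = c(5, 9), local_glyph = c(8, 12),
         local_glyph_dense = c(12, 20), rings = c(8, 20),
         hotspot = c(0, 9), c(0, 20))
}

#' Approximate group boundaries by convex hulls of member boundaries
#'
#' Dissolving member polygons into exact group outlines requires polygon
#' union; as a light-weight stand-in this takes the convex hull of all
#' member boundary vertices (exact for convex groups such as lattice
#' bands).  Supply real group outlines via a boundaries GeoJSON to override.
#'
#' @param boundaries Named list of member geometries (WGS84).
#' @param groups Named character vector: member id -> group label.
#' @return Named list of hull geometries keyed by group label.
#' @export
group_boundary_hulls <- function(boundaries, groups) {
  labels <- sort(unique(groups))
  out <- list()
  for (g in labels) {
    ids <- names(groups)[groups == g]
    ids <- intersect(ids, names(boundaries))
    if (!length(ids)) next
    pts <- do.call(rbind, lapply(ids, function(id)
      do.call(rbind, boundaries[[id]]$rings)))
    h <- grDevices::chull(pts[, 1], pts[, 2])
    ring <- pts[c(h, h[1]), , drop = FALSE]
    out[[g]] <- list(type = "Polygon", rings = list(ring), coords = "wgs84")
  }
  out
}
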
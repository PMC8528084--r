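# --- GeoJSON (RFC 7946) emission and parsing -------------------------------
#
# Feature geometry travels internally either in projected metres (glyphs,
# rings) or already in WGS84 (boundaries).  On write, projected rings are
# inverse-projected, exterior rings are forced counter-clockwise (the RFC
# right-hand rule) and coordinates are rounded to 6 decimal places (~0.1 m).

# ensure a lon/lat ring is closed and wound counter-clockwise
orient_ring_ccw <- function(ring) {
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  if (ring_signed_area(ring) < 0) {
    ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  }
  ring
}

feature_to_wgs84 <- function(feature, crs) {
  geom <- feature$geometry
  if (identical(geom$coords, "projected")) {
    if (is.null(crs)) {
      stop("layer holds projected geometry but has no CRS", call. = FALSE)
    }
    geom$rings <- lapply(geom$rings, function(r) {
      ll <- unproject_points(r[, 1], r[, 2], crs)
      cbind(ll$lon, ll$lat)
    })
    geom$coords <- "wgs84"
  }
  geom$rings <- lapply(geom$rings, function(r) round(r, 6))
  if (geom$type == "Polygon") {
    geom$rings <- lapply(geom$rings, orient_ring_ccw)
  }
  feature$geometry <- geom
  feature
}

geometry_json <- function(geom) {
  if (geom$type == "Point") {
    list(type = "Point", coordinates = as.vector(geom$rings[[1]][1, ]))
  } else if (geom$type == "Polygon") {
    list(type = "Polygon",
         coordinates = lapply(geom$rings, function(r) {
           lapply(seq_len(nrow(r)), function(i) as.vector(r[i, ]))
         }))
  } else if (geom$type == "MultiPolygon") {
    # rings carries a flat list; polygon membership in geom$parts
    list(type = "MultiPolygon",
         coordinates = lapply(geom$parts, function(part) {
           lapply(geom$rings[part], function(r) {
             lapply(seq_len(nrow(r)), function(i) as.vector(r[i, ]))
           })
         }))
  } else {
    stop("unsupported geometry type: ", geom$type, call. = FALSE)
  }
}

#' Write a feature layer as a GeoJSON FeatureCollection
#'
#' Emits RFC 7946 GeoJSON: WGS84 longitude-latitude order, closed rings,
#' counter-clockwise exterior rings, coordinates rounded to 6 decimal
#' places.  Projected glyph geometry is inverse-projected through the
#' layer's CRS.
#'
#' @param layer A `feature_layer`.
#' @param path Output path (`.geojson`).
#' @return `path`, invisibly.
#' @seealso [read_geojson()], [write_layer_sidecar()]
#' @export
write_geojson <- function(layer, path) {
  feats <- lapply(layer$features, function(f) {
    f <- feature_to_wgs84(f, layer$crs)
    list(type = "Feature",
         geometry = geometry_json(f$geometry),
         properties = f$properties)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

parse_geojson_geometry <- function(g) {
  coords_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  if (g$type == "Point") {
    list(type = "Point",
         rings = list(matrix(c(g$coordinates[[1]], g$coordinates[[2]]),
                             ncol = 2)),
         coords = "wgs84")
  } else if (g$type == "Polygon") {
    list(type = "Polygon",
         rings = lapply(g$coordinates, coords_to_matrix),
         coords = "wgs84")
  } else if (g$type == "MultiPolygon") {
    rings <- list(); parts <- list()
    for (poly in g$coordinates) {
      idx <- length(rings) + seq_along(poly)
      rings <- c(rings, lapply(poly, coords_to_matrix))
      parts[[length(parts) + 1L]] <- idx
    }
    list(type = "MultiPolygon", rings = rings, parts = parts,
         coords = "wgs84")
  } else {
    stop("unsupported geometry type: ", g$type, call. = FALSE)
  }
}

#' Read a GeoJSON FeatureCollection
#'
#' Supports Point, Polygon and MultiPolygon features.
#'
#' @param path Path to a `.geojson` file.
#' @return A list with `features` (each with `geometry` and `properties`)
#'   of class `feature_collection`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  features <- lapply(j$features, function(f) {
    list(geometry = parse_geojson_geometry(f$geometry),
         properties = f$properties)
  })
  structure(list(features = features), class = "feature_collection")
}

#' Read boundary polygons keyed by record id
#'
#' @param path GeoJSON FeatureCollection of Polygon/MultiPolygon features.
#' @param id_property Property holding the record id (default
#'   `"record_id"`).
#' @return Named list of geometries keyed by id, for [build_choropleth()].
#' @export
read_boundaries <- function(path, id_property = "record_id") {
  fc <- read_geojson(path)
  out <- list()
  for (f in fc$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      stop("boundary feature without '", id_property, "' property",
           call. = FALSE)
    }
    out[[as.character(id)]] <- f$geometry
  }
  out
}

#' Write a layer's styling / metadata sidecar
#'
#' The sidecar is a small JSON file next to the GeoJSON holding rendering
#' metadata that GeoJSON itself has no slot for: the layer role, advisory
#' zoom-range scale hints, and the choropleth legend (class breaks,
#' colours, labels).
#'
#' @param layer A `feature_layer`.
#' @param path Output path (conventionally `<layer>.style.json`).
#' @return `path`, invisibly.
#' @export
write_layer_sidecar <- function(layer, path) {
  hint <- layer$scale_hint
  if (is.null(hint)) hint <- default_scale_hint(layer$role)
  side <- list(role = layer$role,
               n_features = length(layer$features),
               scale_hint = list(min_zoom = unname(hint[1]),
                                 max_zoom = unname(hint[2])))
  if (!is.null(layer$legend)) {
    side$legend <- lapply(seq_len(nrow(layer$legend)), function(i)
      as.list(layer$legend[i, ]))
  }
  if (!is.null(layer$crs)) {
    side$source_crs <- if (!is.na(layer$crs$epsg))
      paste0("EPSG:", layer$crs$epsg) else layer$crs$name
  }
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
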
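#' Glyph drawing parameters
#'
#' @param radius_max Maximum glyph radius in metres (a slice with score 1
#'   reaches this radius).
#' @param arc_step Maximum angular spacing of arc vertices, degrees; smaller
#'   values give smoother wedges and larger files.  The default 5 keeps the
#'   polygon area within 0.2 percent of the true sector area.
#' @param min_radius_fraction Radius floor as a fraction of `radius_max`, so
#'   zero-score slices remain visible and clickable; set 0 to disable.
#' @param start_bearing Bearing (degrees clockwise from north) where the
#'   first slice starts.
#' @return An object of class `glyph_spec`.
#' @export
glyph_spec <- function(radius_max = 20000, arc_step = 5,
                       min_radius_fraction = 0.01, start_bearing = 0) {
  if (!is.numeric(radius_max) || radius_max <= 0) {
    stop("radius_max must be positive", call. = FALSE)
  }
  if (!is.numeric(arc_step) || arc_step <= 0 || arc_step > 90) {
    stop("arc_step must be in (0, 90] degrees", call. = FALSE)
  }
  if (min_radius_fraction < 0 || min_radius_fraction > 1) {
    stop("min_radius_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(radius_max = radius_max, arc_step = arc_step,
                 min_radius_fraction = min_radius_fraction,
                 start_bearing = start_bearing),
            class = "glyph_spec")
}

#' Angular sectors for a set of slice weights
#'
#' Slice *i* gets angular width `360 * w_i / sum(w)`.  Sectors are
#' contiguous, start at `start_bearing` and proceed clockwise (the ToxPi
#' visual convention); the last sector absorbs any floating-point remainder
#' so the widths sum to exactly 360 degrees.
#'
#' @param weights Positive slice weights.
#' @param start_bearing Starting bearing, degrees clockwise from north.
#' @return Matrix with columns `start` and `end` (bearings in degrees;
#'   `end` >= `start`, measured clockwise from north, may exceed 360).
#' @export
slice_angles <- function(weights, start_bearing = 0) {
  if (length(weights) < 1L || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("all slice weights must be positive and finite", call. = FALSE)
  }
  widths <- 360 * weights / sum(weights)
  ends <- start_bearing + cumsum(widths)
  ends[length(ends)] <- start_bearing + 360  # close the disc exactly
  starts <- c(start_bearing, ends[-length(ends)])
  cbind(start = starts, end = ends)
}

# bearing (deg clockwise from north) -> unit vector in projected x/y
bearing_xy <- function(bearing_deg) {
  b <- bearing_deg * pi / 180
  cbind(x = sin(b), y = cos(b))
}

#' Build one wedge polygon
#'
#' The ring runs centre -> arc (clockwise from `start` to `end` bearing, one
#' vertex at least every `arc_step` degrees) -> centre, and is closed
#' (first vertex equals last).  As `arc_step` shrinks the polygon area
#' converges to the circular-sector area `(theta / 2) * r^2`.
#'
#' @param cx,cy Glyph centre in projected metres.
#' @param start,end Bearings in degrees clockwise from north; `end` must be
#'   strictly greater than `start` (clockwise extent).
#' @param radius Wedge radius in metres.
#' @param arc_step Maximum degrees between arc vertices.
#' @return Numeric matrix with columns `x`, `y`; a closed, non-self-
#'   intersecting ring containing the centre vertex.
#' @export
build_wedge <- function(cx, cy, start, end, radius, arc_step = 5) {
  if (!is.finite(radius) || radius <= 0) {
    stop("wedge radius must be positive", call. = FALSE)
  }
  if (end <= start) {
    stop("wedge must have positive clockwise extent (end > start)",
         call. = FALSE)
  }
  width <- end - start
  nseg <- max(1L, ceiling(width / arc_step))
  bearings <- start + width * (0:nseg) / nseg
  uv <- bearing_xy(bearings)
  ring <- cbind(x = cx + radius * uv[, "x"], y = cy + radius * uv[, "y"])
  if (width >= 360 - 1e-9) {
    # full disc: no radial edges; close on the first arc vertex
    rbind(ring, ring[1, , drop = FALSE])
  } else {
    rbind(c(cx, cy), ring, c(cx, cy))
  }
}

#' Build a maximum-radius ring (circle polygon)
#'
#' @param cx,cy Centre in projected metres.
#' @param radius Circle radius in metres.
#' @param arc_step Maximum degrees between vertices.
#' @return Closed ring matrix with `360 / arc_step + 1` vertices (for
#'   `arc_step` dividing 360).
#' @export
build_ring <- function(cx, cy, radius, arc_step = 5) {
  if (!is.finite(radius) || radius <= 0) {
    stop("ring radius must be positive", call. = FALSE)
  }
  nseg <- max(3L, ceiling(360 / arc_step))
  bearings <- 360 * (0:nseg) / nseg
  uv <- bearing_xy(bearings)
  cbind(x = cx + radius * uv[, "x"], y = cy + radius * uv[, "y"])
}

#' Build all wedge polygons of one ToxPi glyph
#'
#' One wedge per (selected) slice, with angular width proportional to the
#' slice weight and radius `max(score, min_radius_fraction) * radius_max`.
#' When a subset of slices is drawn, angles are recomputed from the subset's
#' weights so the subset still tiles the full disc.
#'
#' @param slice_scores Named numeric vector of slice scores in \[0, 1\]
#'   (names matching the model's slices).
#' @param model A [toxpi_model()].
#' @param cx,cy Glyph centre in projected metres.
#' @param spec A [glyph_spec()].
#' @param slices Optional character vector selecting a subset of slices.
#' @return A list of wedges; each element has `ring` (coordinate matrix)
#'   and `slice`, `domain`, `color`, `score`, `weight_fraction` attributes.
#' @export
build_glyph <- function(slice_scores, model, cx, cy, spec = glyph_spec(),
                        slices = NULL) {
  sn <- slice_names(model)
  if (is.null(slices)) {
    slices <- sn
  } else {
    unknown <- setdiff(slices, sn)
    if (length(unknown)) {
      stop("unknown slice name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  idx <- match(slices, sn)
  w <- slice_weights(model)[idx]
  ang <- slice_angles(w, spec$start_bearing)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    s <- model$slices[[idx[k]]]
    sc <- slice_scores[[s$name]]
    if (is.null(sc) || !is.finite(sc)) {
      stop("no score for slice '", s$name, "'", call. = FALSE)
    }
    # radius floor keeps every wedge a valid (clickable) polygon
    r <- max(sc, spec$min_radius_fraction, 1e-9) * spec$radius_max
    ring <- build_wedge(cx, cy, ang[k, "start"], ang[k, "end"], r,
                        spec$arc_step)
    out[[k]] <- list(ring = ring, slice = s$name, domain = s$domain,
                     color = s$color, score = sc,
                     weight_fraction = w[k] / sum(w))
  }
  out
}

# shoelace signed area of a closed ring (positive = counter-clockwise)
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}
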
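#' Metres per statute mile
#' @export
METERS_PER_MILE <- 1609.344

# mean Earth radius (m) used for haversine neighbourhoods
EARTH_RADIUS_M <- 6371008.8

#' Distance-band spatial weights
#'
#' Binary neighbourhoods on great-circle (haversine) distance: *j* is a
#' neighbour of *i* when `d(i, j) <= band` (inclusive), and every point is
#' its own neighbour, as the Gi* statistic requires.  Distances are
#' computed on the unprojected WGS84 coordinates so the neighbourhood
#' structure does not depend on the drawing CRS.
#'
#' @param lat,lon Numeric vectors of WGS84 coordinates (>= 2 points).
#' @param band Band distance in metres (e.g. `50 * METERS_PER_MILE`).
#' @return An object of class `spatial_weights`: a list with `neighbors`
#'   (list of integer index vectors, self included) and `band`.  Records
#'   whose only neighbour is themselves trigger a warning but are retained.
#' @export
build_distance_band_weights <- function(lat, lon, band) {
  n <- length(lat)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  if (!is.numeric(band) || band <= 0) {
    stop("band must be a positive distance in metres", call. = FALSE)
  }
  pts <- cbind(lon, lat)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    d <- geosphere::distHaversine(pts[i, ], pts, r = EARTH_RADIUS_M)
    neighbors[[i]] <- which(d <= band)
  }
  lonely <- which(vapply(neighbors, length, integer(1)) == 1L)
  if (length(lonely)) {
    warning(length(lonely), " record(s) have no neighbour within the band",
            " besides themselves")
  }
  structure(list(neighbors = neighbors, band = band, n = n),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  sizes <- vapply(x$neighbors, length, integer(1))
  cat("Distance-band spatial weights: ", x$n, " records, band ",
      x$band, " m, mean neighbours ", round(mean(sizes), 2), "\n", sep = "")
  invisible(x)
}

#' Getis-Ord Gi* statistic
#'
#' For each record *i*, with binary weights `w_ij` over its neighbourhood
#' (self included):
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2] / (n - 1)}}}
#' with \eqn{\bar X = \sum_j x_j / n} and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar X^2}}.  The statistic is itself a
#' z-score.  Degenerate cases — constant values (`S = 0`) or a band so wide
#' that every point neighbours every other (zero variance term) — yield
#' `z = 0` with a warning rather than an error.
#'
#' @param values Finite numeric vector, one value per record.
#' @param weights A `spatial_weights` object over the same records.
#' @return Numeric vector of Gi* z-scores.
#' @export
gi_star <- function(values, weights) {
  n <- weights$n
  if (length(values) != n) {
    stop("values and weights describe different numbers of records",
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (n < 2L) stop("need at least two records", call. = FALSE)
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    nb <- weights$neighbors[[i]]
    wsum <- length(nb)             # binary weights: sum w = sum w^2 = |nb|
    u2 <- (n * wsum - wsum^2) / (n - 1)
    if (s == 0 || u2 <= 0) {
      z[i] <- 0
      degenerate <- TRUE
      next
    }
    z[i] <- (sum(values[nb]) - xbar * wsum) / (s * sqrt(u2))
  }
  if (degenerate) {
    warning("degenerate Gi* denominator (constant values or all-inclusive ",
            "band); affected z-scores set to 0")
  }
  z
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; adjusted values are
#' monotone in rank and never smaller than the raw p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Seven-bin hotspot confidence classification
#'
#' Each record is assigned an integer bin in `-3..3`: `|bin| = 3` at the
#' 99 percent confidence level (`p <= 0.01`), `2` at 95 percent
#' (`p <= 0.05`), `1` at 90 percent (`p <= 0.10`), otherwise `0`; the sign
#' follows the Gi* z-score (positive = hotspot, negative = coldspot).  With
#' unadjusted two-sided normal p-values this reproduces the classic
#' `|z|` cutoffs 1.645 / 1.960 / 2.576.
#'
#' @param z Gi* z-scores.
#' @param p Significance values (raw or FDR-adjusted), same length.
#' @return Integer vector of bins in `{-3, -2, -1, 0, 1, 2, 3}`.
#' @export
assign_bins <- function(z, p) {
  if (length(z) != length(p)) {
    stop("z and p must have equal length", call. = FALSE)
  }
  mag <- ifelse(p <= 0.01, 3L, ifelse(p <= 0.05, 2L, ifelse(p <= 0.10, 1L, 0L)))
  as.integer(mag * sign(z))
}

#' Hotspot analysis of ToxPi scores
#'
#' End-to-end Getis-Ord Gi* pipeline on the overall ToxPi score or any
#' single slice score: distance-band weights, Gi* z-scores, two-sided
#' normal p-values, optional Benjamini-Hochberg adjustment across records,
#' and the seven-bin confidence classification.
#'
#' @param scores A `toxpi_scores` data frame.
#' @param field Score column to analyse: `"overall"` (default) or a slice
#'   name.
#' @param band_miles Distance band in statute miles (default 50).
#' @param fdr Apply FDR adjustment before binning (default `TRUE`).
#' @return A data frame joined to the input attributes: `record_id`, `lat`,
#'   `lon`, `value`, `gi_z`, `p`, `p_adj` (`NA` when `fdr = FALSE`) and
#'   `bin`; one row per input record, in input order.
#' @examples
#' \dontrun{
#' hs <- hotspot_analysis(scores, field = "overall", band_miles = 50)
#' table(hs$bin)
#' }
#' @export
hotspot_analysis <- function(scores, field = "overall", band_miles = 50,
                             fdr = TRUE) {
  if (!field %in% names(scores)) {
    stop("unknown score field: '", field, "'; available: overall, ",
         paste(slice_names(attr(scores, "model")), collapse = ", "),
         call. = FALSE)
  }
  values <- scores[[field]]
  w <- build_distance_band_weights(scores$lat, scores$lon,
                                   band = band_miles * METERS_PER_MILE)
  z <- gi_star(values, w)
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (fdr) adjust_fdr(p) else rep(NA_real_, length(p))
  bin <- assign_bins(z, if (fdr) p_adj else p)
  data.frame(record_id = scores$record_id, lat = scores$lat,
             lon = scores$lon, value = values, gi_z = z, p = p,
             p_adj = p_adj, bin = bin, stringsAsFactors = FALSE)
}

# diverging hot/cold colours for the seven bins (-3..3)
hotspot_bin_colors <- c("-3" = "#08519C", "-2" = "#3182BD", "-1" = "#BDD7E7",
                        "0" = "#F0F0F0",
                        "1" = "#FCAE91", "2" = "#DE2D26", "3" = "#A50F15")

#' Build a bin-coloured hotspot layer
#'
#' Colours each record's boundary polygon (or a point marker when no
#' boundary is available) by its hotspot confidence bin, hot red to cold
#' blue.
#'
#' @param hotspots Output of [hotspot_analysis()].
#' @param boundaries Optional named list of boundary geometries keyed by
#'   record id (WGS84); records without one become point features.
#' @return A `feature_layer` with role `hotspot`.
#' @export
build_hotspot_layer <- function(hotspots, boundaries = NULL) {
  features <- lapply(seq_len(nrow(hotspots)), function(i) {
    id <- hotspots$record_id[i]
    props <- list(record_id = id, value = hotspots$value[i],
                  gi_z = hotspots$gi_z[i], p = hotspots$p[i],
                  p_adj = hotspots$p_adj[i], bin = hotspots$bin[i],
                  color = unname(hotspot_bin_colors[
                    as.character(hotspots$bin[i])]))
    if (!is.null(boundaries) && id %in% names(boundaries)) {
      geom <- boundaries[[id]]
      geom$coords <- "wgs84"
      list(geometry = geom, properties = props)
    } else {
      list(geometry = list(type = "Point",
                           rings = list(cbind(hotspots$lon[i],
                                              hotspots$lat[i])),
                           coords = "wgs84"),
           properties = props)
    }
  })
  feature_layer("hotspot", features, crs = NULL)
}
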
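#' Equal-area projected coordinate reference systems
#'
#' Glyph polygons are drawn in projected metres so that a glyph of a given
#' radius covers the same ground area anywhere on the map.  The package
#' implements the ellipsoidal Albers equal-area conic projection and ships
#' definitions for two common EPSG codes:
#'
#' * `5070` — NAD83 / Conus Albers (default; continental United States)
#' * `3310` — NAD83 / California Albers
#'
#' Custom Albers parameterisations can be built with [albers_crs()].
#'
#' @param epsg Integer EPSG code.
#' @return An object of class `toxpigis_crs` describing the projection.
#' @examples
#' crs <- crs_lookup(5070)
#' p <- project_points(35, -80, crs)
#' unproject_points(p$x, p$y, crs)
#' @export
crs_lookup <- function(epsg) {
  epsg <- as.integer(epsg)
  switch(as.character(epsg),
    "5070" = albers_crs(lat1 = 29.5, lat2 = 45.5, lat0 = 23, lon0 = -96,
                        x0 = 0, y0 = 0, epsg = 5070,
                        name = "NAD83 / Conus Albers"),
    "3310" = albers_crs(lat1 = 34, lat2 = 40.5, lat0 = 0, lon0 = -120,
                        x0 = 0, y0 = -4000000, epsg = 3310,
                        name = "NAD83 / California Albers"),
    stop("unknown EPSG code: ", epsg,
         "; known codes: 5070, 3310 (or use albers_crs())", call. = FALSE)
  )
}

#' Construct a custom Albers equal-area conic CRS
#'
#' @param lat1,lat2 Standard parallels (degrees).  Scale along a parallel is
#'   exactly 1 at the standard parallels.
#' @param lat0,lon0 Latitude and longitude of origin (degrees).
#' @param x0,y0 False easting / northing (metres).
#' @param epsg Optional EPSG code carried as metadata.
#' @param name Descriptive name.
#' @return A `toxpigis_crs` object.  The ellipsoid is GRS80
#'   (`a = 6378137`, `1/f = 298.257222101`).
#' @export
albers_crs <- function(lat1, lat2, lat0, lon0, x0 = 0, y0 = 0,
                       epsg = NA_integer_, name = "custom Albers") {
  a <- 6378137
  f <- 1 / 298.257222101
  e2 <- f * (2 - f)
  e <- sqrt(e2)
  rad <- pi / 180
  m <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  q <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) -
                  (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  if (abs(lat1 + lat2) < 1e-9 && abs(lat1 - lat2) > 1e-9) {
    stop("standard parallels symmetric about the equator degenerate the ",
         "conic (n = 0); choose asymmetric parallels", call. = FALSE)
  }
  phi1 <- lat1 * rad; phi2 <- lat2 * rad; phi0 <- lat0 * rad
  m1 <- m(phi1); m2 <- m(phi2)
  q1 <- q(phi1); q2 <- q(phi2)
  n <- if (abs(phi1 - phi2) < 1e-12) sin(phi1) else
    (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  rho0 <- a * sqrt(C - n * q(phi0)) / n
  structure(list(a = a, e = e, e2 = e2, n = n, C = C, rho0 = rho0,
                 lon0 = lon0, x0 = x0, y0 = y0, epsg = epsg, name = name,
                 q = q),
            class = "toxpigis_crs")
}

#' @export
print.toxpigis_crs <- function(x, ...) {
  cat("Projected CRS: ", x$name,
      if (!is.na(x$epsg)) paste0(" (EPSG:", x$epsg, ")"), "\n", sep = "")
  invisible(x)
}

#' Project WGS84 coordinates to planar metres
#'
#' @param lat,lon Numeric vectors of decimal degrees.
#' @param crs A `toxpigis_crs` from [crs_lookup()] or [albers_crs()].
#' @return A list with numeric vectors `x` and `y` (metres).
#' @export
project_points <- function(lat, lon, crs) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  rad <- pi / 180
  phi <- lat * rad
  theta <- crs$n * (lon - crs$lon0) * rad
  rho <- crs$a * sqrt(crs$C - crs$n * crs$q(phi)) / crs$n
  list(x = crs$x0 + rho * sin(theta),
       y = crs$y0 + crs$rho0 - rho * cos(theta))
}

#' Inverse-project planar metres back to WGS84 coordinates
#'
#' The latitude is recovered by Newton-style fixed-point iteration on the
#' authalic-latitude relation, to a tolerance well below 1e-6 degrees.
#'
#' @param x,y Numeric vectors of projected metres.
#' @param crs A `toxpigis_crs`.
#' @return A list with numeric vectors `lat` and `lon` (degrees).
#' @export
unproject_points <- function(x, y, crs) {
  deg <- 180 / pi
  xp <- x - crs$x0
  yp <- crs$rho0 - (y - crs$y0)
  rho <- sqrt(xp^2 + yp^2)
  theta <- atan2(xp * sign(crs$n), yp * sign(crs$n))
  qv <- (crs$C - (rho * crs$n / crs$a)^2) / crs$n
  e <- crs$e; e2 <- crs$e2
  phi <- asin(pmin(1, pmax(-1, qv / 2)))
  for (it in 1:25) {
    s <- sin(phi)
    delta <- (1 - e2 * s^2)^2 / (2 * cos(phi)) *
      (qv / (1 - e2) - s / (1 - e2 * s^2) +
         (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
    delta[!is.finite(delta)] <- 0  # poles: cos(phi) = 0
    phi <- phi + delta
    if (max(abs(delta)) < 1e-14) break
  }
  list(lat = phi * deg, lon = crs$lon0 + theta * deg / crs$n)
}
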
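# shared fixtures and independent oracles

# small 3-slice model exercising weights, directions and multi-component slices
tiny_model <- function() {
  toxpi_model("tiny", list(
    toxpi_slice("alpha", list(toxpi_component("a1"),
                              toxpi_component("a2", weight = 3)),
                weight = 2, domain = "d1", color = "#FF0000"),
    toxpi_slice("beta", list(toxpi_component("b1", "lower_is_worse")),
                weight = 1, domain = "d2", color = "#00FF00"),
    toxpi_slice("gamma", list(toxpi_component("g1")),
                weight = 1, domain = "d2", color = "#0000FF")))
}

tiny_data <- function() {
  toxpi_data(c("r1", "r2", "r3"),
             lat = c(35, 35.5, 36), lon = c(-80, -80.5, -81),
             values = cbind(a1 = c(10, 20, 30), a2 = c(0, 5, 10),
                            b1 = c(1, 2, 3), g1 = c(0.5, 0.5, 1.5)))
}

random_scores <- function(n, model, seed) {
  set.seed(seed)
  ss <- matrix(runif(n * length(model$slices)), nrow = n,
               dimnames = list(NULL, slice_names(model)))
  toxpi_scores(sprintf("r%03d", seq_len(n)),
               lat = runif(n, 30, 45), lon = runif(n, -110, -80),
               slice_scores = ss, model = model)
}

# independent haversine, coded from the definition
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * R * asin(sqrt(a))
}

# brute-force double-loop Gi*, straight from the formula definition,
# independent of the package's vectorised neighbour-list implementation
gi_star_brute <- function(values, lat, lon, band) {
  n <- length(values)
  xbar <- sum(values) / n
  s <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n)) {
      w[j] <- as.numeric(haversine_oracle(lat[i], lon[i],
                                          lat[j], lon[j]) <= band)
    }
    num <- sum(w * values) - xbar * sum(w)
    den <- s * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1))
    z[i] <- if (den == 0) 0 else num / den
  }
  z
}

# ray-casting point-in-polygon, used as a geometric oracle
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# shoelace area of a closed ring (centred first to avoid cancellation at
# large projected offsets)
ring_area <- function(ring) {
  x <- ring[, 1] - mean(ring[, 1]); y <- ring[, 2] - mean(ring[, 2])
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# polygon centroid (area-weighted, shoelace form)
ring_centroid <- function(ring) {
  ctr <- colMeans(ring[-1, , drop = FALSE])
  ring <- cbind(ring[, 1] - ctr[1], ring[, 2] - ctr[2])
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1
  cr <- x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n]
  a <- sum(cr) / 2
  ctr + c(sum((x[1:n] + x[2:(n + 1)]) * cr) / (6 * a),
          sum((y[1:n] + y[2:(n + 1)]) * cr) / (6 * a))
}
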
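test_that("slice angles partition the circle proportionally to weight", {
  a <- slice_angles(c(1, 1, 1, 1))
  expect_equal(unname(a[, "end"] - a[, "start"]), rep(90, 4))
  a <- slice_angles(c(2, 1, 1))
  expect_equal(unname(a[, "end"] - a[, "start"]), c(180, 90, 90))
  a <- slice_angles(1)
  expect_equal(unname(a[, "end"] - a[, "start"]), 360)
  expect_error(slice_angles(c(1, 0)), "positive")
})

test_that("angular widths always sum to exactly 360 degrees", {
  set.seed(4)
  for (rep in 1:25) {
    w <- runif(sample(1:20, 1), 0.01, 10)
    a <- slice_angles(w, start_bearing = runif(1, 0, 360))
    expect_equal(sum(a[, "end"] - a[, "start"]), 360, tolerance = 1e-9)
    # contiguous
    if (nrow(a) > 1) {
      expect_equal(unname(a[-1, "start"]), unname(a[-nrow(a), "end"]))
    }
  }
})

test_that("a full-circle wedge approximates the disc area", {
  r <- 1000
  ring <- build_wedge(0, 0, 0, 360, r, arc_step = 5)
  # regular n-gon oracle: (n/2) r^2 sin(2*pi/n)
  n <- 72
  a_ngon <- (n / 2) * r^2 * sin(2 * pi / n)
  expect_equal(ring_area(ring), a_ngon, tolerance = 1e-9)
  expect_lt(abs(ring_area(ring) - pi * r^2) / (pi * r^2), 0.002)
})

test_that("wedges follow the clockwise-from-north convention", {
  ring <- build_wedge(10, 20, 0, 90, 5, arc_step = 5)
  # first vertex is the centre, second the arc start pointing due north
  expect_equal(unname(ring[1, ]), c(10, 20))
  expect_equal(unname(ring[2, ]), c(10, 25))
  # last arc vertex points due east
  expect_equal(unname(ring[nrow(ring) - 1, ]), c(15, 20), tolerance = 1e-9)
  expect_error(build_wedge(0, 0, 45, 45, 5), "positive clockwise extent")
  expect_error(build_wedge(0, 0, 0, 90, 0), "radius must be positive")
})

test_that("wedge rings are closed with at least four vertices", {
  ring <- build_wedge(0, 0, 17, 63, 100, arc_step = 5)
  expect_gte(nrow(ring), 4)
  expect_equal(ring[1, ], ring[nrow(ring), ])
})

test_that("rings have the expected vertex count and perimeter", {
  ring <- build_ring(0, 0, 1000, arc_step = 5)
  expect_equal(nrow(ring), 360 / 5 + 1)
  seg <- diff(ring)
  per <- sum(sqrt(rowSums(seg^2)))
  expect_lt(abs(per - 2 * pi * 1000) / (2 * pi * 1000), 0.0015)
})

test_that("glyph wedges respect the score-to-radius mapping", {
  m <- tiny_model()
  spec <- glyph_spec(radius_max = 1000, min_radius_fraction = 0.01)
  g <- build_glyph(c(alpha = 0, beta = 0.5, gamma = 1), m, 0, 0, spec)
  radii <- vapply(g, function(w)
    max(sqrt(rowSums(w$ring^2))), numeric(1))
  expect_equal(radii, c(0.01, 0.5, 1) * 1000, tolerance = 1e-9)
})

test_that("all-ones glyph tiles the full disc and is centred", {
  m <- pvi_like_model()
  spec <- glyph_spec(radius_max = 500, arc_step = 5)
  sc <- stats::setNames(rep(1, 14), slice_names(m))
  g <- build_glyph(sc, m, 100, 200, spec)
  areas <- vapply(g, function(w) ring_area(w$ring), numeric(1))
  # union covers the disc up to arc discretization (< 0.2% at 5 degrees)
  expect_lt(abs(sum(areas) - pi * 500^2) / (pi * 500^2), 0.002)
  # area-weighted centroid of the union sits on the glyph centre
  cents <- t(vapply(g, function(w) ring_centroid(w$ring), numeric(2)))
  ctr <- colSums(cents * areas) / sum(areas)
  expect_lt(max(abs(ctr - c(100, 200))), 1e-6 * 500)
})

test_that("a slice subset re-partitions the circle over its own weights", {
  m <- pvi_like_model()
  sc <- stats::setNames(runif(14), slice_names(m))
  sub <- slice_names(m)[c(1, 5, 9)]
  g <- build_glyph(sc, m, 0, 0, glyph_spec(radius_max = 100), slices = sub)
  expect_length(g, 3)
  expect_identical(vapply(g, `[[`, character(1), "slice"), sub)
  expect_equal(sum(vapply(g, `[[`, numeric(1), "weight_fraction")), 1)
  expect_error(build_glyph(sc, m, 0, 0, slices = c("nope", "Testing Rates")),
               "nope")
})

test_that("wedges of one glyph are pairwise interior-disjoint", {
  m <- tiny_model()
  set.seed(13)
  for (rep in 1:5) {
    sc <- stats::setNames(runif(3, 0.2, 1), slice_names(m))
    g <- build_glyph(sc, m, 0, 0, glyph_spec(radius_max = 100))
    # interior probes: mid-bearing points at half radius of each wedge
    for (i in seq_along(g)) {
      probe <- ring_centroid(g[[i]]$ring)
      expect_true(point_in_ring(probe[1], probe[2], g[[i]]$ring))
      for (j in seq_along(g)) {
        if (i != j) expect_false(point_in_ring(probe[1], probe[2],
                                               g[[j]]$ring))
      }
    }
  }
})

test_that("doubling the radius quadruples wedge areas", {
  m <- tiny_model()
  sc <- stats::setNames(c(0.4, 0.7, 1), slice_names(m))
  g1 <- build_glyph(sc, m, 0, 0, glyph_spec(radius_max = 100))
  g2 <- build_glyph(sc, m, 0, 0, glyph_spec(radius_max = 200))
  a1 <- vapply(g1, function(w) ring_area(w$ring), numeric(1))
  a2 <- vapply(g2, function(w) ring_area(w$ring), numeric(1))
  expect_equal(a2 / a1, rep(4, 3), tolerance = 1e-9)
})

test_that("rings contain every wedge of the same glyph", {
  m <- tiny_model()
  sc <- stats::setNames(runif(3), slice_names(m))
  spec <- glyph_spec(radius_max = 300)
  g <- build_glyph(sc, m, 50, 50, spec)
  ring <- build_ring(50, 50, spec$radius_max, spec$arc_step)
  rmax <- max(sqrt((ring[, 1] - 50)^2 + (ring[, 2] - 50)^2))
  for (w in g) {
    d <- sqrt((w$ring[, 1] - 50)^2 + (w$ring[, 2] - 50)^2)
    expect_true(all(d <= rmax + 1e-9))
  }
})
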
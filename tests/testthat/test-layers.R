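test_that("local glyph layer has one wedge per record and slice", {
  m <- tiny_model()
  sc <- random_scores(3, m, seed = 1)
  layer <- build_local_glyph_layer(sc)
  expect_s3_class(layer, "feature_layer")
  expect_identical(layer$role, "local_glyph")
  expect_length(layer$features, 3 * 3)
  props <- names(layer$features[[1]]$properties)
  expect_true(all(c("record_id", "slice", "domain", "slice_score",
                    "weight_fraction", "color", "overall") %in% props))
  # all features share the attribute schema
  for (f in layer$features) {
    expect_identical(names(f$properties), props)
  }
})

test_that("glyph layer carries raw component values for popups", {
  m <- tiny_model()
  d <- tiny_data()
  sc <- suppressMessages(toxpi_score(d, m))
  layer <- build_local_glyph_layer(sc, data = d)
  f_alpha <- layer$features[[1]]
  expect_identical(f_alpha$properties$slice, "alpha")
  expect_equal(f_alpha$properties$a1, 10)
  expect_equal(f_alpha$properties$a2, 0)
})

test_that("empty inputs give an empty but valid layer", {
  m <- tiny_model()
  sc <- random_scores(1, m, seed = 2)[0, ]
  attr(sc, "model") <- m
  layer <- build_local_glyph_layer(sc)
  expect_length(layer$features, 0)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  fc <- read_geojson(path)
  expect_length(fc$features, 0)
})

test_that("duplicate record ids are rejected", {
  m <- tiny_model()
  sc <- random_scores(3, m, seed = 3)
  sc$record_id[2] <- sc$record_id[1]
  expect_error(build_local_glyph_layer(sc), "duplicate")
})

test_that("dense layer shrinks areas by shrink^2 but keeps attributes", {
  m <- tiny_model()
  sc <- random_scores(4, m, seed = 4)
  spec <- glyph_spec(radius_max = 1000)
  local <- build_local_glyph_layer(sc, spec)
  dense <- build_dense_layer(sc, spec, shrink = 0.5)
  expect_identical(dense$role, "local_glyph_dense")
  expect_length(dense$features, length(local$features))
  for (k in seq_along(local$features)) {
    expect_identical(dense$features[[k]]$properties,
                     local$features[[k]]$properties)
    a_l <- ring_area(local$features[[k]]$geometry$rings[[1]])
    a_d <- ring_area(dense$features[[k]]$geometry$rings[[1]])
    expect_equal(a_d / a_l, 0.25, tolerance = 1e-9)
  }
  expect_error(build_dense_layer(sc, spec, shrink = 1), "between 0 and 1")
  expect_error(build_dense_layer(sc, spec, shrink = 0), "between 0 and 1")
})

test_that("rings layer has one circle per record", {
  m <- tiny_model()
  sc <- random_scores(3, m, seed = 5)
  rl <- build_rings_layer(sc, glyph_spec(radius_max = 2000))
  expect_identical(rl$role, "rings")
  expect_length(rl$features, 3)
})

test_that("group glyph layer draws one glyph per group with its label", {
  m <- pvi_like_model()
  sc <- random_scores(10, m, seed = 6)
  groups <- stats::setNames(rep(c("east", "west"), each = 5), sc$record_id)
  med <- aggregate_group_medians(sc, groups)
  layer <- build_group_glyph_layer(med)
  expect_identical(layer$role, "group_glyph")
  expect_length(layer$features, 2 * 14)
  labs <- unique(vapply(layer$features, function(f)
    f$properties$group, character(1)))
  expect_identical(sort(labs), c("east", "west"))
})

test_that("quantile choropleth classes partition the observed range", {
  scores <- seq(0.1, 1.0, by = 0.1)
  legend <- choropleth_classes(scores, k = 5)
  expect_equal(nrow(legend), 5)
  expect_equal(legend$lower[1], min(scores))
  expect_equal(legend$upper[5], max(scores))
  # contiguous, non-overlapping
  expect_equal(legend$lower[-1], legend$upper[-5])
  # two records per class for uniform ranks
  cls <- toxpigis:::classify_values(scores, legend)
  expect_equal(unname(table(cls)), rep(2L, 5), ignore_attr = TRUE)
})

test_that("degenerate and short score vectors collapse class counts", {
  expect_warning(legend <- choropleth_classes(rep(0.5, 8), k = 5),
                 "single class")
  expect_equal(nrow(legend), 1)
  expect_error(choropleth_classes(runif(10), k = 1), "at least 2")
})

test_that("choropleth layers attribute boundaries and skip missing ones", {
  m <- tiny_model()
  sc <- random_scores(4, m, seed = 7)
  sq <- function(lon, lat) list(type = "Polygon", coords = "wgs84",
    rings = list(cbind(c(lon, lon + 1, lon + 1, lon, lon),
                       c(lat, lat, lat + 1, lat + 1, lat))))
  boundaries <- stats::setNames(
    lapply(1:3, function(i) sq(-90 + i, 35)), sc$record_id[1:3])
  expect_warning(layer <- build_choropleth(sc, boundaries, k = 2),
                 "skipped")
  expect_length(layer$features, 3)
  f <- layer$features[[1]]
  expect_identical(f$properties$record_id, sc$record_id[1])
  expect_equal(f$properties$score, sc$overall[1])
  expect_true(f$properties$class %in% seq_len(nrow(layer$legend)))
  expect_error(build_choropleth(sc, boundaries, value = "nope"),
               "unknown score field")
})

test_that("scale hints are advisory metadata only", {
  m <- tiny_model()
  sc <- random_scores(2, m, seed = 8)
  layer <- build_local_glyph_layer(sc)
  before <- layer$features
  layer2 <- attach_scale_hints(layer, 5, 12)
  expect_identical(layer2$features, before)
  expect_equal(unname(layer2$scale_hint), c(5, 12))
  expect_error(attach_scale_hints(layer, 10, 5), "must not exceed")
  # hints serialize into the sidecar
  path <- withr::local_tempfile(fileext = ".json")
  write_layer_sidecar(layer2, path)
  side <- jsonlite::fromJSON(path)
  expect_equal(side$scale_hint$min_zoom, 5)
  expect_equal(side$scale_hint$max_zoom, 12)
  expect_identical(side$role, "local_glyph")
})

test_that("group hulls cover member boundaries", {
  sq <- function(lon, lat) list(type = "Polygon", coords = "wgs84",
    rings = list(cbind(c(lon, lon + 1, lon + 1, lon, lon),
                       c(lat, lat, lat + 1, lat + 1, lat))))
  boundaries <- list(a = sq(0, 0), b = sq(1, 0), c = sq(5, 5))
  groups <- c(a = "g1", b = "g1", c = "g2")
  hulls <- group_boundary_hulls(boundaries, groups)
  expect_identical(names(hulls), c("g1", "g2"))
  h1 <- hulls$g1$rings[[1]]
  expect_equal(range(h1[, 1]), c(0, 2))
  expect_equal(range(h1[, 2]), c(0, 1))
})
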
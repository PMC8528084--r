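test_that("GeoJSON write/read round-trips feature counts and attributes", {
  m <- tiny_model()
  sc <- random_scores(3, m, seed = 1)
  layer <- build_local_glyph_layer(sc, glyph_spec(radius_max = 5000))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  fc <- read_geojson(path)
  expect_length(fc$features, length(layer$features))
  for (k in seq_along(layer$features)) {
    p_in <- layer$features[[k]]$properties
    p_out <- fc$features[[k]]$properties
    expect_identical(p_out$record_id, p_in$record_id)
    expect_identical(p_out$slice, p_in$slice)
    expect_equal(p_out$slice_score, p_in$slice_score)
    expect_equal(p_out$overall, p_in$overall)
  }
})

test_that("emitted polygons satisfy RFC 7946 structural rules", {
  m <- tiny_model()
  sc <- random_scores(5, m, seed = 2)
  layer <- build_local_glyph_layer(sc, glyph_spec(radius_max = 3000))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  fc <- read_geojson(path)
  for (f in fc$features) {
    ring <- f$geometry$rings[[1]]
    # closed ring
    expect_equal(ring[1, ], ring[nrow(ring), ])
    # right-hand rule: exterior ring counter-clockwise
    expect_gt(toxpigis:::ring_signed_area(ring), 0)
    # WGS84 lon-lat order and plausible ranges
    expect_true(all(ring[, 1] >= -180 & ring[, 1] <= 180))
    expect_true(all(ring[, 2] >= -90 & ring[, 2] <= 90))
  }
})

test_that("coordinates are serialized at six decimal places", {
  m <- tiny_model()
  sc <- random_scores(1, m, seed = 3)
  layer <- build_local_glyph_layer(sc, glyph_spec(radius_max = 1000))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  coord_blocks <- regmatches(
    txt, gregexpr('"coordinates":\\[\\[.*?\\]\\]\\]', txt))[[1]]
  nums <- unlist(regmatches(coord_blocks,
                            gregexpr("-?[0-9]+\\.[0-9]+", coord_blocks)))
  expect_gt(length(nums), 0)
  decimals <- nchar(sub("^-?[0-9]+\\.", "", nums))
  expect_true(all(decimals <= 6))
})

test_that("glyph geometry survives projection to within write precision", {
  m <- tiny_model()
  sc <- random_scores(1, m, seed = 4)
  spec <- glyph_spec(radius_max = 10000)
  layer <- build_local_glyph_layer(sc, spec)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  fc <- read_geojson(path)
  crs <- crs_lookup(5070)
  ctr <- project_points(sc$lat, sc$lon, crs)
  for (f in fc$features) {
    ring <- f$geometry$rings[[1]]
    p <- project_points(ring[, 2], ring[, 1], crs)
    d <- sqrt((p$x - ctr$x)^2 + (p$y - ctr$y)^2)
    # all vertices within radius_max (+ rounding slack ~0.2 m)
    expect_true(all(d <= spec$radius_max + 0.5))
  }
})

test_that("an empty layer writes a valid empty FeatureCollection", {
  layer <- feature_layer("local_glyph", list())
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(j$type, "FeatureCollection")
  expect_length(j$features, 0)
})

test_that("data CSV reader validates ids, coordinates and numerics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lat,lon,x,y", "a,35,-80,1,2", "b,36,-81,3,4",
               "c,37,-82,5,6"), path)
  d <- read_data_csv(path)
  expect_length(d$ids, 3)
  expect_identical(colnames(d$values), c("x", "y"))

  writeLines(c("id,lat,lon,x", "a,35,-80,1", "a,36,-81,2"), path)
  expect_error(read_data_csv(path), "duplicate record id.*a")

  writeLines(c("id,lat,lon,x", "a,100,-80,1", "b,36,-81,2"), path)
  expect_error(read_data_csv(path), "latitude out of range")

  writeLines(c("id,lat,lon,x", "a,35,-80,oops", "b,36,-81,2"), path)
  expect_error(read_data_csv(path), "non-numeric value 'oops' at line 2")

  expect_error(read_data_csv("no/such.csv"), "not found")
  writeLines(c("id,lat,lon,x", "a,35,-80,1"), path)
  expect_error(read_data_csv(path, id_col = "fips"), "fips")
})

test_that("pre-scored CSV reader validates against the model", {
  m <- tiny_model()
  sc <- random_scores(4, m, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(sc, path)
  back <- read_prescored_csv(path, m, id_col = "record_id")
  expect_equal(back$overall, sc$overall, tolerance = 1e-9)
  expect_equal(score_matrix(back), score_matrix(sc), tolerance = 1e-9)
  # overall consistent with recomputation under model weights
  expect_equal(back$overall,
               compute_overall(score_matrix(back), slice_weights(m)),
               tolerance = 1e-9)

  df <- utils::read.csv(path, check.names = FALSE)
  df$alpha <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_prescored_csv(path, m, id_col = "record_id"), "alpha")

  write_scores_csv(sc, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$mystery <- 1
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_prescored_csv(path, m, id_col = "record_id"), "mystery")

  df$mystery <- NULL
  df$beta[1] <- 1.7
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_prescored_csv(path, m, id_col = "record_id"), "outside \\[0, 1\\]")
})

test_that("boundary reader keys geometries by record id", {
  sq <- list(type = "Polygon", coords = "wgs84",
             rings = list(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))))
  layer <- feature_layer("local_choropleth", list(
    list(geometry = sq, properties = list(record_id = "a")),
    list(geometry = sq, properties = list(record_id = "b"))))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  b <- read_boundaries(path)
  expect_identical(names(b), c("a", "b"))
  expect_identical(b$a$type, "Polygon")
})
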
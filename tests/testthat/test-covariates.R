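test_that("distance_to_class matches brute force and handles edge cases", {
  spec <- tiny_spec(3)
  lc <- raster_grid(spec, matrix(match("cropland", LANDCOVER_CLASSES), 3, 3),
                    categories = LANDCOVER_CLASSES)
  lc$values[2, 2] <- match("forest", LANDCOVER_CLASSES)
  d <- distance_to_class(lc, "forest")
  expect_equal(d$values[2, 2], 0)
  expect_equal(d$values[1, 1], 30 * sqrt(2), tolerance = 1e-9) # 42.43 m
  expect_equal(d$values[1, 2], 30)

  # saturated target
  allf <- raster_grid(spec, matrix(match("forest", LANDCOVER_CLASSES), 3, 3))
  expect_true(all(distance_to_class(allf, "forest")$values == 0))

  # empty target is an explicit error
  expect_error(distance_to_class(lc, "water"), "empty target")

  # brute-force oracle on an irregular mask
  spec2 <- grid_spec(7, 9, 30)
  set.seed(42)
  mask <- matrix(stats::runif(63) < 0.15, 7, 9)
  mask[3, 4] <- TRUE
  lc2 <- raster_grid(spec2, matrix(1, 7, 9))
  d2 <- distance_to_class(lc2, NULL, target_mask = mask)
  expect_equal(d2$values, brute_distance(mask, spec2), tolerance = 1e-9)
})

test_that("distance layers are Lipschitz and rotation-equivariant", {
  spec <- grid_spec(12, 12, 30)
  set.seed(3)
  mask <- matrix(stats::runif(144) < 0.1, 12, 12)
  mask[5, 5] <- TRUE
  lc <- raster_grid(spec, matrix(1, 12, 12))
  d <- distance_to_class(lc, NULL, target_mask = mask)$values
  # neighbouring pixels differ by at most their centre separation
  expect_true(all(abs(diff(d)) <= 30 + 1e-9))
  expect_true(all(abs(t(diff(t(d)))) <= 30 + 1e-9))

  rot <- distance_to_class(lc, NULL,
                           target_mask = t(mask[12:1, ]))$values
  expect_equal(rot, t(d[12:1, ]), tolerance = 1e-12)
})

test_that("focal_stats: constants, brute-force window, errors", {
  spec <- tiny_spec(5)
  const <- raster_grid(spec, matrix(7, 5, 5))
  expect_true(all(focal_stats(const, 60, "sd")$values == 0))
  expect_true(all(focal_stats(const, 60, "mean")$values == 7))

  rowlay <- raster_grid(spec, matrix(rep(1:5, 5), 5, 5))
  fm <- focal_stats(rowlay, 60, "mean")
  # centre pixel: 13 cells within 60 m (radius 2 px, circular)
  expect_equal(fm$values[3, 3],
               brute_focal(rowlay$values, spec, 3, 3, 60, "mean"))
  fs <- focal_stats(rowlay, 60, "sd")
  expect_equal(fs$values[3, 3],
               brute_focal(rowlay$values, spec, 3, 3, 60, "sd"),
               tolerance = 1e-12)
  # edge pixel uses in-extent cells only
  expect_equal(fm$values[1, 1],
               brute_focal(rowlay$values, spec, 1, 1, 60, "mean"))

  expect_error(focal_stats(const, 10, "mean"), "radius")

  # focal mean bounded by layer range
  set.seed(1)
  lay <- raster_grid(spec, matrix(stats::rnorm(25), 5, 5))
  m <- focal_stats(lay, 90, "mean")$values
  expect_true(all(m >= min(lay$values) - 1e-12 &
                    m <= max(lay$values) + 1e-12))
})

test_that("percent_class_in_window saturates and matches pixel counting", {
  spec <- grid_spec(20, 20, 30)
  f <- match("forest", LANDCOVER_CLASSES)
  g <- match("grassland", LANDCOVER_CLASSES)
  allf <- raster_grid(spec, matrix(f, 20, 20), categories = LANDCOVER_CLASSES)
  expect_true(all(percent_class_in_window(allf, "forest")$values == 100))
  expect_true(all(percent_class_in_window(allf, "grassland")$values == 0))

  # half-plane forest, boundary pixel, radius 250 at 30 m
  half <- matrix(g, 20, 20); half[, 1:10] <- f
  hp <- raster_grid(spec, half, categories = LANDCOVER_CLASSES)
  got <- percent_class_in_window(hp, "forest", 250)$values[10, 10]
  ind <- matrix(as.numeric(half == f), 20, 20)
  expect_equal(got, 100 * brute_focal(ind, spec, 10, 10, 250, "mean"),
               tolerance = 1e-9)
})

test_that("correlation_filter: greedy order and threshold behaviour", {
  set.seed(7)
  x <- stats::rnorm(500)
  # identical columns: first kept, second dropped
  expect_identical(correlation_filter(data.frame(a = x, b = x)), "a")

  make_pair <- function(r) r * x + sqrt(1 - r^2) * stats::rnorm(500)
  hi <- make_pair(0.8); lo <- make_pair(0.6)
  expect_gt(abs(stats::cor(x, hi)), 0.7)  # construction sanity
  expect_lt(abs(stats::cor(x, lo)), 0.7)
  expect_identical(correlation_filter(data.frame(a = x, b = hi)), "a")
  expect_identical(correlation_filter(data.frame(a = x, b = lo)),
                   c("a", "b"))

  # single covariate retained; zero variance dropped with warning
  expect_identical(correlation_filter(data.frame(a = x)), "a")
  expect_warning(k <- correlation_filter(data.frame(a = x, z = rep(1, 500))),
                 "zero-variance")
  expect_identical(k, "a")

  # retained set verified against direct pairwise correlations
  df <- data.frame(a = x, b = hi, c = lo, d = stats::rnorm(500))
  kept <- correlation_filter(df)
  cm <- abs(stats::cor(df[, kept]))
  expect_true(all(cm[upper.tri(cm)] < 0.7))
})

test_that("build_stack emits the documented layer set and extracts points", {
  b <- fixture_bundle()
  st <- build_stack(b)
  expect_identical(length(st$layers), 18L)
  expect_identical(st$provenance, "baseline")
  expect_true(all(c("canopy_closure", "dist_forest", "dist_river",
                    "dist_road", "dist_settlement", "dist_plantation",
                    "ndvi", "pct_forest_250", "pop_density",
                    "canopy_height", "cc_mean_150", "cc_sd_500",
                    "ndvi_sd_150", "ndvi_mean_500") %in% names(st$layers)))
  for (nm in grep("^dist_", names(st$layers), value = TRUE))
    expect_true(all(st$layers[[nm]]$values >= 0))
  expect_true(all(st$layers$pct_forest_250$values >= 0 &
                    st$layers$pct_forest_250$values <= 100))

  pts <- pixel_centres(b$landcover$spec, rep(3, 10), 1:10)
  tab <- extract_stack(st, pts[, 1], pts[, 2])
  expect_identical(nrow(tab), 10L)
  expect_identical(ncol(tab), 3L + 18L)

  # missing settlements propagate a named empty-target error
  b2 <- generate_landscape(
    grid_spec(20, 20),
    default_landscape_config(
      proportions = c(forest = 0.5, grassland = 0.2, cropland = 0.3,
                      water = 0, settlement = 0),
      n_rivers = 1, plantation = TRUE),
    seed = 2)
  expect_error(build_stack(b2), "dist_settlement")
})

test_that("rotating the landcover rotates derived layers identically", {
  spec <- grid_spec(15, 15, 30)
  set.seed(5)
  v <- matrix(sample(c(1, 2, 3), 225, replace = TRUE), 15, 15)
  lc <- raster_grid(spec, v, categories = LANDCOVER_CLASSES)
  lcr <- raster_grid(spec, t(v[15:1, ]), categories = LANDCOVER_CLASSES)
  for (fn in list(function(l) distance_to_class(l, "forest"),
                  function(l) percent_class_in_window(l, "forest", 90))) {
    a <- fn(lc)$values
    b <- fn(lcr)$values
    expect_equal(b, t(a[15:1, ]), tolerance = 1e-9)
  }
})
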
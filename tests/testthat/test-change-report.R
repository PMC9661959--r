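test_that("delta_raster arithmetic, bounds and grid checks", {
  spec <- tiny_spec(4)
  b <- raster_grid(spec, matrix(0.4, 4, 4))
  s <- raster_grid(spec, matrix(0.6, 4, 4))
  d <- delta_raster(b, s)
  expect_equal(d$values, matrix(0.2, 4, 4), tolerance = 1e-12)
  expect_true(all(delta_raster(b, b)$values == 0))
  expect_true(all(abs(d$values) <= 1))

  s$values[2, 2] <- NA
  expect_true(is.na(delta_raster(b, s)$values[2, 2]))
  expect_error(delta_raster(b, raster_grid(tiny_spec(5), matrix(0, 5, 5))),
               "grid mismatch")
})

test_that("high_risk_change_mask categorises by strict threshold", {
  spec <- tiny_spec(2)
  b <- raster_grid(spec, matrix(c(0.4, 0.6, 0.5, 0.7), 2))
  s <- raster_grid(spec, matrix(c(0.6, 0.6, 0.5, 0.3), 2))
  m <- high_risk_change_mask(b, s)
  lab <- HIGH_RISK_CATEGORIES[m$values]
  expect_identical(lab[1], "new_high")     # 0.4 -> 0.6
  expect_identical(lab[2], "stable_high")  # 0.6 -> 0.6
  expect_identical(lab[3], "stable_low")   # 0.5 -> 0.5 (strict >)
  expect_identical(lab[4], "lost_high")    # 0.7 -> 0.3
  # categories partition the raster
  expect_true(all(m$values %in% 1:4))
})

test_that("sample_random_points: determinism, exhaustion, capacity", {
  spec <- tiny_spec(6)
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  p1 <- sample_random_points(mask, 5, seed = 3, spec = spec)
  p2 <- sample_random_points(mask, 5, seed = 3, spec = spec)
  expect_identical(p1, p2)
  expect_identical(nrow(unique(p1[, c("row", "col")])), 5L)
  expect_true(all(mask[cbind(p1$row, p1$col)]))

  all16 <- sample_random_points(mask, 16, seed = 1, spec = spec)
  expect_setequal(paste(all16$row, all16$col),
                  paste(which(mask, arr.ind = TRUE)[, 1],
                        which(mask, arr.ind = TRUE)[, 2]))
  expect_error(sample_random_points(mask, 17, seed = 1, spec = spec),
               "capacity error")
})

test_that("aggregate_change means members and propagates null scenarios", {
  spec <- grid_spec(10, 10, 30)
  bv <- matrix(0.3, 10, 10)
  sv <- bv; sv[, 1:5] <- sv[, 1:5] + 0.2
  rs <- list(metricA = list(baseline = raster_grid(spec, bv),
                            scenario = raster_grid(spec, sv)))
  pts <- pixel_centres(spec, c(2, 2, 8), c(2, 8, 2))
  units <- data.frame(unit_id = c("p1", "p2", "p3"), unit = "plot",
                      x = pts[, 1], y = pts[, 2])
  units <- rbind(units,
                 data.frame(unit_id = "habA", unit = "habitat",
                            x = pts[, 1], y = pts[, 2]))
  ct <- aggregate_change(rs, units)
  p <- ct[ct$unit == "plot", ]
  expect_equal(p$delta[p$unit_id == "p1"], 0.2)
  expect_equal(p$delta[p$unit_id == "p2"], 0)
  hab <- ct[ct$unit == "habitat", ]
  # habitat delta = mean of member deltas (+0.2, 0, +0.2)
  expect_equal(hab$delta, mean(c(0.2, 0, 0.2)))

  # null scenario propagates zero deltas at every level
  rs0 <- list(metricA = list(baseline = raster_grid(spec, bv),
                             scenario = raster_grid(spec, bv)))
  expect_true(all(aggregate_change(rs0, units)$delta == 0))
})

test_that("riparian buffers through cropland raise local crop-raiding risk", {
  # constructed layout: cropland band along a mid-raster river, forest at
  # both margins, grassland near the top margin (far from the buffer, with
  # its own nearby forest so its risk covariate is untouched)
  spec <- grid_spec(60, 60, 30)
  v <- matrix(match("grassland", LANDCOVER_CLASSES), 60, 60)
  v[25:36, ] <- match("cropland", LANDCOVER_CLASSES)
  v[c(1:3, 58:60), ] <- match("forest", LANDCOVER_CLASSES)
  lc <- raster_grid(spec, v, categories = LANDCOVER_CLASSES)
  river <- list(cbind(x = c(0, 1800), y = rep(1800 - 30.5 * 30, 2)))
  # risk declines with distance to forest
  dist_f <- distance_to_class(lc, "forest")
  risk_b <- raster_grid(spec, stats::plogis(1 - dist_f$values / 200))
  cfg <- scenario_config(60)
  lc2 <- apply_riparian_buffer(lc, river, cfg)
  dist_f2 <- distance_to_class(lc2, "forest")
  risk_s <- raster_grid(spec, stats::plogis(1 - dist_f2$values / 200))

  crop <- v == match("cropland", LANDCOVER_CLASSES)
  far_grass <- v == match("grassland", LANDCOVER_CLASSES) &
    distance_to_polylines(spec, river)$values > 560 &
    dist_f$values < 500  # far from buffer but with stable forest distance
  expect_gt(sum(far_grass), 0)
  rs <- list(risk = list(baseline = risk_b, scenario = risk_s))
  idx_c <- which(crop); idx_g <- which(far_grass)
  rc_c <- arrayInd(idx_c, dim(v)); rc_g <- arrayInd(idx_g, dim(v))
  units <- rbind(
    data.frame(unit_id = "cropland", unit = "habitat",
               x = pixel_centres(spec, rc_c[, 1], rc_c[, 2])[, 1],
               y = pixel_centres(spec, rc_c[, 1], rc_c[, 2])[, 2]),
    data.frame(unit_id = "far_grassland", unit = "habitat",
               x = pixel_centres(spec, rc_g[, 1], rc_g[, 2])[, 1],
               y = pixel_centres(spec, rc_g[, 1], rc_g[, 2])[, 2]))
  ct <- aggregate_change(rs, units)
  expect_gt(ct$delta[ct$unit_id == "cropland"], 0)
  expect_equal(ct$delta[ct$unit_id == "far_grassland"], 0)
})

test_that("habitat_summary: group arithmetic, ANOVA calibration and power", {
  set.seed(71)
  hab <- rep(c("forest", "cropland", "grassland"), times = c(12, 48, 7))
  val <- stats::rnorm(67, mean = c(forest = 41, cropland = 11,
                                   grassland = 8)[hab], sd = 14)
  hs <- habitat_summary(hab, val)
  for (h in unique(hab)) {
    expect_equal(hs$summary$mean[hs$summary$habitat == h],
                 mean(val[hab == h]))
    expect_equal(hs$summary$sd[hs$summary$habitat == h],
                 stats::sd(val[hab == h]))
  }
  expect_lt(hs$anova$p, 0.001)
  expect_identical(nrow(hs$tukey), 3L)

  # single habitat: tests skipped with a note
  hs1 <- habitat_summary(rep("forest", 10), stats::rnorm(10))
  expect_null(hs1$anova)
  expect_match(hs1$note, "single habitat")

  # null calibration: equal means give a roughly uniform ANOVA p
  ps <- vapply(1:200, function(i)
    habitat_summary(rep(c("a", "b"), each = 10),
                    stats::rnorm(20))$anova$p, numeric(1))
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.10)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # power: 30 vs 40 with sd 2, n = 20 each, Tukey p < 0.001
  hab2 <- rep(c("x", "y"), each = 20)
  val2 <- stats::rnorm(40, mean = ifelse(hab2 == "x", 30, 40), sd = 2)
  hs2 <- habitat_summary(hab2, val2)
  expect_lt(hs2$tukey$p_adj[1], 0.001)
})
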
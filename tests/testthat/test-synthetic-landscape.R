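test_that("generate_landscape is deterministic and honours composition", {
  spec <- grid_spec(100, 100)
  b1 <- generate_landscape(spec, seed = 5)
  b2 <- generate_landscape(spec, seed = 5)
  expect_identical(b1$landcover$values, b2$landcover$values)
  expect_identical(b1$canopy_closure$values, b2$canopy_closure$values)
  expect_identical(b1$rivers, b2$rivers)

  cfg <- default_landscape_config()
  prop <- table(factor(LANDCOVER_CLASSES[b1$landcover$values],
                       levels = LANDCOVER_CLASSES)) / (100 * 100)
  # realized class shares within 10 percentage points of request at 100x100
  expect_true(all(abs(prop - cfg$proportions[names(prop)]) < 0.10))

  # convergence: tighter at 200x200
  b3 <- generate_landscape(grid_spec(200, 200), seed = 5)
  prop3 <- table(factor(LANDCOVER_CLASSES[b3$landcover$values],
                        levels = LANDCOVER_CLASSES)) / (200 * 200)
  expect_true(all(abs(prop3 - cfg$proportions[names(prop3)]) < 0.05))

  # bundle invariants
  expect_true(all(b1$canopy_closure$values >= 0 &
                    b1$canopy_closure$values <= 100))
  expect_true(all(abs(b1$ndvi$values) <= 1))
  expect_true(all(b1$pop_density$values >= 0))
  fmask <- b1$landcover$values == match("forest", LANDCOVER_CLASSES)
  cmask <- b1$landcover$values == match("cropland", LANDCOVER_CLASSES)
  expect_gt(mean(b1$canopy_closure$values[fmask]),
            mean(b1$canopy_closure$values[cmask]))
  # water pixels trace the river polylines
  wmask <- b1$landcover$values == match("water", LANDCOVER_CLASSES)
  d <- distance_to_polylines(spec, b1$rivers)
  expect_lt(max(d$values[wmask]), spec$resolution)
})

test_that("generate_landscape degenerate and error cases", {
  spec <- grid_spec(20, 20)
  cfg <- default_landscape_config(
    proportions = c(forest = 1, grassland = 0, cropland = 0, water = 0,
                    settlement = 0),
    n_rivers = 0, plantation = FALSE)
  b <- generate_landscape(spec, cfg, seed = 1)
  expect_true(all(b$landcover$values == match("forest", LANDCOVER_CLASSES)))
  expect_length(b$rivers, 0)

  bad <- default_landscape_config()
  bad$proportions["forest"] <- 0.9
  expect_error(generate_landscape(spec, bad, 1), "sum to 1")
  cfg2 <- default_landscape_config(n_villages = 0)
  expect_error(generate_landscape(spec, cfg2, 1), "n_villages")
  expect_error(generate_landscape(grid_spec(2, 2),
                                  default_landscape_config(), 1),
               "capacity")
})

test_that("generate_species_pool counts, diets and threat fractions", {
  p <- generate_species_pool(0, 5, seed = 7)
  expect_identical(table(p$taxon)[["mammal"]], 5L)
  expect_false("bird" %in% p$taxon)

  p2 <- generate_species_pool(30, 20, seed = 2, p_threatened = 0.2)
  sums <- p2$diet_invertebrate + p2$diet_vertebrate + p2$diet_plant_seed +
    p2$diet_other
  expect_true(all(abs(sums - 1) < 1e-9))
  n_thr <- sum(p2$threat_status %in% c("VU", "EN", "CR"))
  expect_gt(n_thr, 3); expect_lt(n_thr, 18)  # ~10 of 50 expected

  expect_error(generate_species_pool(-1, 5, 1), "argument error")
  expect_error(generate_species_pool(0, 0, 1), "argument error")
})

test_that("simulate_point_surveys: noise-free limit, determinism, bounds", {
  b <- fixture_bundle()
  st <- build_stack(b)
  pool <- generate_species_pool(20, 10, seed = 3)
  pr <- default_response_params()
  pr$t_ground <- c(intercept = 36.5, slope = -0.117, sd = 0)
  sv <- simulate_point_surveys(b, st, pool, pr, seed = 4)
  expect_equal(sv$plots$t_ground, 36.5 - 0.117 * sv$plots$canopy_closure,
               tolerance = 1e-12)
  expect_setequal(unique(sv$plots$habitat),
                  c("forest", "woodland", "grassland", "cropland"))
  expect_true(all(is.na(sv$plots$yield[sv$plots$habitat != "cropland"])))

  sv2 <- simulate_point_surveys(b, st, pool, pr, seed = 4)
  expect_identical(sv$detections, sv2$detections)

  out_xy <- cbind(1e6, 1e6)
  expect_error(simulate_point_surveys(b, st, pool, pr, seed = 1,
                                      survey_xy = out_xy),
               "outside the raster extent")
})

test_that("zero class separation decouples richness from covariates", {
  b <- fixture_bundle(seed = 21)
  st <- build_stack(b)
  pool <- generate_species_pool(25, 25, seed = 3)
  pr <- default_response_params()
  pr$richness$mammal["sep"] <- 0
  pr$richness$bird["sep"] <- 0
  sv <- simulate_point_surveys(b, st, pool, pr, seed = 8, n_survey = 500)
  det <- sv$detections[sv$detections$taxon == "mammal", ]
  cnt <- table(factor(det$location_id,
                      levels = sv$survey_locations$location_id))
  pf <- extract_at(st$layers$pct_forest_250, sv$survey_locations$x,
                   sv$survey_locations$y)
  cls <- richness_classes(as.numeric(cnt), 3)$labels
  bins <- cut(pf, stats::quantile(pf, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  p <- suppressWarnings(stats::chisq.test(table(cls, bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("simulate_conflict_events matches the monitored point counts", {
  b <- fixture_bundle()
  crop <- b$landcover$values == match("cropland", LANDCOVER_CLASSES)
  spec <- b$landcover$spec
  risk <- raster_grid(spec, matrix(stats::runif(spec$n_rows * spec$n_cols),
                                   spec$n_rows))
  ev <- simulate_conflict_events(risk, seed = 2, cropland_mask = crop)
  expect_identical(sum(ev$outcome == "presence"), 308L)
  expect_identical(sum(ev$outcome == "absence"), 97L)
  expect_true(all(crop[cbind(cell_from_xy(spec, ev$x, ev$y))]))
  expect_gt(mean(ev$risk[ev$outcome == "presence"]),
            mean(ev$risk[ev$outcome == "absence"]))

  # flat surface: no risk gradient between outcomes
  flat <- raster_grid(spec, matrix(0.5, spec$n_rows, spec$n_cols))
  ev2 <- simulate_conflict_events(flat, 50, 50, seed = 3,
                                  cropland_mask = crop)
  expect_equal(mean(ev2$risk[ev2$outcome == "presence"]),
               mean(ev2$risk[ev2$outcome == "absence"]))

  # degenerate risk: all presences land on the single high-risk pixel
  v <- matrix(0, spec$n_rows, spec$n_cols)
  hot <- which(crop)[1]
  v[hot] <- 1
  ev3 <- simulate_conflict_events(raster_grid(spec, v), 10, 5, seed = 4,
                                  cropland_mask = crop)
  pres <- ev3[ev3$outcome == "presence", ]
  rc <- arrayInd(hot, dim(v))
  ctr <- pixel_centres(spec, rc[, 1], rc[, 2])
  expect_true(all(pres$x == ctr[1, 1] & pres$y == ctr[1, 2]))

  expect_error(
    simulate_conflict_events(risk, 1e6, 97, 1, cropland_mask = crop),
    "capacity error")
})

test_that("simulate_households: counts, ranges and degenerate thresholds", {
  hh <- simulate_households(seed = 6)
  expect_identical(nrow(hh), 461L)
  expect_identical(length(unique(hh$village)), 6L)
  expect_true(all(hh$perception %in% 0:4))
  sch <- default_indicator_schema()
  for (i in seq_len(nrow(sch)))
    expect_true(all(hh[[sch$name[i]]] >= sch$min[i] &
                      hh[[sch$name[i]]] <= sch$max[i]))

  co <- default_household_coef(6)
  co$thresholds <- rep(-Inf, 4)
  hh2 <- simulate_households(50, coef = co, seed = 1)
  expect_true(all(hh2$perception == 4))

  co$thresholds <- rep(Inf, 4)
  hh3 <- simulate_households(50, coef = co, seed = 1)
  expect_true(all(hh3$perception == 0))

  expect_error(simulate_households(0), "argument error")
  expect_error(simulate_households(10, villages = character(0)),
               "argument error")
})

test_that("zero wellbeing coefficient decouples perception from wellbeing", {
  co <- default_household_coef(6)
  co$beta_wellbeing <- 0
  co$wellbeing <- list(kind = "uniform")
  hh <- simulate_households(2000, coef = co, seed = 9)
  rho <- stats::cor(hh$wellbeing_index, hh$perception, method = "spearman")
  expect_lt(abs(rho), 0.06)
})
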
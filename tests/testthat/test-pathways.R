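test_that("classify_guild follows the dominant-diet rule", {
  expect_identical(
    classify_guild(list(diet_plant_seed = 0.6, diet_invertebrate = 0.4,
                        diet_vertebrate = 0, diet_other = 0)),
    "plant_seed")
  # 50% exactly is not dominant
  expect_identical(
    classify_guild(list(diet_plant_seed = 0.5, diet_invertebrate = 0.5,
                        diet_vertebrate = 0, diet_other = 0)),
    "none")
  expect_identical(
    classify_guild(list(diet_invertebrate = 1, diet_vertebrate = 0,
                        diet_plant_seed = 0, diet_other = 0)),
    "invertebrate")
  # residual "other" dominating is still no guild
  expect_identical(
    classify_guild(list(diet_invertebrate = 0.2, diet_vertebrate = 0.1,
                        diet_plant_seed = 0.1, diet_other = 0.6)),
    "none")
  expect_error(
    classify_guild(list(diet_invertebrate = 0.7, diet_vertebrate = 0.7,
                        diet_plant_seed = 0, diet_other = 0)),
    "validation error")
})

test_that("flag_threatened follows the IUCN rule", {
  expect_true(flag_threatened("EN"))
  expect_identical(flag_threatened(c("VU", "EN", "CR")), rep(TRUE, 3))
  expect_false(flag_threatened("LC"))
  expect_false(flag_threatened("DD"))
  expect_error(flag_threatened("XX"), "validation error")
})

test_that("richness_classes splits on quantiles with ties to the low side", {
  rc <- richness_classes(1:9, 3)
  expect_identical(as.integer(table(rc$labels)), c(3L, 3L, 3L))
  expect_identical(as.character(rc$labels[1:3]), rep("low", 3))

  rc2 <- richness_classes(c(0, 10), 2)
  expect_identical(as.character(rc2$labels), c("low", "high"))

  expect_error(richness_classes(rep(3, 10), 3), "degenerate counts")
  # ties at the threshold go low
  rc3 <- richness_classes(c(1, 2, 2, 5), 2)
  expect_identical(as.character(rc3$labels), c("low", "low", "low", "high"))
})

test_that("fit_pathway1 chooses sensible models per response", {
  b <- fixture_bundle()
  st <- build_stack(b)
  pool <- generate_species_pool(10, 10, 2)
  sv <- simulate_point_surveys(b, st, pool, seed = 3)
  p1 <- fit_pathway1(sv$plots)
  expect_identical(p1$t_ground$chosen, "glm")
  expect_lt(p1$t_ground$fit$coefficients[["slope"]], 0)
  expect_true(all(names(p1$yields) %in% c("okra", "sugarcane", "maize")))

  # noise-free linear input is fit perfectly
  pr <- default_response_params()
  pr$t_ground["sd"] <- 0
  sv0 <- simulate_point_surveys(b, st, pool, pr, seed = 3)
  p10 <- fit_pathway1(sv0$plots)
  expect_equal(p10$t_ground$fit$deviance_explained, 1, tolerance = 1e-9)

  expect_error(fit_pathway1(sv$plots[, -5]), "schema error")
})

test_that("fit_pathway2 recovers an informative covariate end to end", {
  set.seed(44)
  n <- 150
  grad <- stats::runif(n, 0, 100)
  pts <- data.frame(location_id = sprintf("L%03d", 1:n),
                    x = stats::runif(n, 0, 3000),
                    y = stats::runif(n, 0, 3000),
                    informative = grad,
                    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  lab <- ifelse(grad + stats::rnorm(n, 0, 10) > 50, "high", "low")
  responses <- data.frame(location_id = pts$location_id,
                          metric_id = "mammals_high", label = lab)
  p2 <- fit_pathway2(responses, pts, 0.05)
  mod <- p2$models$mammals_high
  expect_identical(mod$selection$selected[1], "informative")
  expect_s3_class(mod$model, "lda_model")
  # posterior of "high" rises monotonically along the informative gradient
  post <- predict_lda(mod$model,
                      data.frame(informative = seq(0, 100, 10),
                                 noise1 = 0, noise2 = 0))
  expect_true(all(diff(post[, "high"]) > 0))
  expect_true(is.finite(mod$moran$I))

  # single observed class is skipped with a report
  responses$label <- "high"
  p2b <- fit_pathway2(responses, pts, 0.05)
  expect_identical(p2b$skipped$mammals_high, "single observed class")
})

test_that("pathway-2 residual Moran's I is calibrated under iid data", {
  set.seed(55)
  nonsig <- vapply(1:100, function(i) {
    n <- 90
    x <- stats::rnorm(n)
    lab <- ifelse(x + stats::rnorm(n) > 0, "high", "low")
    m <- fit_lda(data.frame(x = x), lab)
    r <- restoscape:::.lda_score_residuals(m, data.frame(x = x), lab)
    co <- cbind(stats::runif(n), stats::runif(n))
    morans_i(r, co)$p_value >= 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("fit_pathway3 finds forest-edge risk and bounds the surface", {
  b <- fixture_bundle(seed = 17)
  st <- build_stack(b)
  spec <- b$landcover$spec
  crop <- b$landcover$values == match("cropland", LANDCOVER_CLASSES)
  risk <- raster_grid(spec, stats::plogis(1.5 - st$layers$dist_forest$values / 150))
  ev <- simulate_conflict_events(risk, 308, 97, seed = 5,
                                 cropland_mask = crop)
  pts <- extract_stack(st, ev$x, ev$y)
  keep <- c("dist_forest", "dist_river", "pop_density", "ndvi",
            "canopy_height")
  p3 <- fit_pathway3(ev, pts[, keep], 0.05)
  expect_true("dist_forest" %in% p3$selection$selected)

  surf <- predict_risk(p3$model, st)
  expect_true(all(surf$values >= 0 & surf$values <= 1))

  # flat generator: no discrimination (AUC ~ 0.5)
  flat <- raster_grid(spec, matrix(0.5, spec$n_rows, spec$n_cols))
  ev0 <- simulate_conflict_events(flat, 308, 97, seed = 6,
                                  cropland_mask = crop)
  pts0 <- extract_stack(st, ev0$x, ev0$y)
  m0 <- fit_lda(pts0[, keep], ev0$outcome)
  sc <- predict_lda(m0, pts0[, keep])[, "presence"]
  auc <- restoscape:::auc_score(sc, ev0$outcome == "presence")
  expect_lt(abs(auc - 0.5), 0.1)

  ev$outcome <- "presence"
  expect_error(fit_pathway3(ev, pts[, keep]), "single outcome class")
})

test_that("scenario predictions move with pct_forest_250 where it increased", {
  b <- fixture_bundle(seed = 23)
  st <- build_stack(b)
  # responses driven by pct_forest_250
  set.seed(1)
  n <- 120
  xy <- pixel_centres(b$landcover$spec,
                      sample(b$landcover$spec$n_rows, n, TRUE),
                      sample(b$landcover$spec$n_cols, n, TRUE))
  pf <- extract_at(st$layers$pct_forest_250, xy[, 1], xy[, 2])
  lab <- ifelse(pf + stats::rnorm(n, 0, 5) > stats::median(pf),
                "high", "low")
  m <- fit_lda(data.frame(pct_forest_250 = pf), lab)
  cfg <- scenario_config(60)
  lc2 <- apply_riparian_buffer(b$landcover, b$rivers, cfg)
  st2 <- rebuild_scenario_stack(b, st, lc2, cfg)
  base <- predict_lda(m, st)$high$values
  scen <- predict_lda(m, st2)$high$values
  inc <- st2$layers$pct_forest_250$values > st$layers$pct_forest_250$values
  expect_true(all(scen[inc] >= base[inc]))
})

test_that("build_biodiversity_responses assembles labelled metrics", {
  b <- fixture_bundle()
  st <- build_stack(b)
  pool <- generate_species_pool(25, 15, seed = 4)
  sv <- simulate_point_surveys(b, st, pool, seed = 5)
  resp <- build_biodiversity_responses(sv$detections, pool,
                                       sv$survey_locations)
  expect_true(all(c("birds_high", "mammals_high", "birds_threatened",
                    "mammals_threatened") %in% resp$metric_id))
  th <- resp[resp$metric_id == "mammals_threatened", ]
  expect_true(all(th$label %in% c("present", "absent")))
  hi <- resp[resp$metric_id == "birds_high", ]
  expect_true(all(hi$label %in% c("low", "medium", "high")))
})
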
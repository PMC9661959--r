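#' Default end-to-end pipeline configuration
#'
#' All seeds are explicit; derived stage seeds are small offsets of the
#' master seed so one `--seed` reproduces the whole run.
#'
#' @param seed Master seed.
#' @param n_rows,n_cols,resolution Grid dimensions.
#' @param out_dir Output directory.
#' @return A validated config list.
#' @export
default_pipeline_config <- function(seed = 1, n_rows = 100, n_cols = 100,
                                    resolution = 30,
                                    out_dir = tempfile("restoscape_run_")) {
  list(
    grid = list(n_rows = n_rows, n_cols = n_cols, resolution = resolution),
    landscape = default_landscape_config(),
    scenario = list(buffer_half_width = 60, attribute_imputation = "mean"),
    models = list(p_enter = 0.05, priors = "empirical", n_classes = 3),
    species = list(n_birds = 40, n_mammals = 20),
    conflict = list(n_presence = 308, n_absence = 97),
    households = list(n = 461),
    sample_points = list(n_smallholder = 50, n_plantation = 50),
    seeds = list(landscape = seed, species = seed + 1, surveys = seed + 2,
                 conflict = seed + 3, households = seed + 4,
                 scenario = seed + 5, sample_points = seed + 6),
    out_dir = out_dir)
}

#' Validate a pipeline configuration
#'
#' Fails fast (before any compute) if required fields or seeds are missing.
#'
#' @param config A config list.
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  need <- c("grid", "landscape", "scenario", "models", "seeds", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config schema error: missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  need_seeds <- c("landscape", "species", "surveys", "conflict",
                  "households", "scenario", "sample_points")
  ms <- setdiff(need_seeds, names(config$seeds))
  if (length(ms))
    stop("config schema error: missing seed(s): ",
         paste(ms, collapse = ", "), call. = FALSE)
  if (!all(vapply(config$seeds, is.numeric, TRUE)))
    stop("config schema error: all seeds must be numeric", call. = FALSE)
  invisible(config)
}

.md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full simulate-fit-scenario-report pipeline
#'
#' Orchestrates the framework end to end on a synthetic landscape:
#' landscape generation, covariate stack, pathway-1 plot models, pathway-2
#' biodiversity LDA models, pathway-3 conflict model, riparian-buffer
#' scenario, baseline/scenario prediction, change aggregation and the
#' wellbeing/perception models. All outputs are written under
#' `config$out_dir` and listed (with md5 checksums) in the returned
#' manifest, which is also written as `manifest.json`.
#'
#' @param config See [default_pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  validate_config(config)
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[restoscape] ", ...)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  spec <- grid_spec(config$grid$n_rows, config$grid$n_cols,
                    config$grid$resolution)
  bundle <- stage("simulate", {
    b <- generate_landscape(spec, config$landscape,
                            config$seeds$landscape)
    add(write_bundle(b, file.path(out, "landscape")))
    b
  })
  stack <- stage("covariates", {
    s <- build_stack(bundle)
    for (nm in names(s$layers))
      add(write_raster(s$layers[[nm]],
                       file.path(out, paste0("baseline_", nm, ".asc"))))
    s
  })
  surveys <- stage("surveys", {
    pool <- generate_species_pool(config$species$n_birds,
                                  config$species$n_mammals,
                                  config$seeds$species)
    sv <- simulate_point_surveys(bundle, stack, pool,
                                 seed = config$seeds$surveys)
    p <- file.path(out, "plots.csv")
    utils::write.csv(sv$plots, p, row.names = FALSE); add(p)
    p <- file.path(out, "detections.csv")
    utils::write.csv(sv$detections, p, row.names = FALSE); add(p)
    c(sv, list(pool = pool))
  })
  fits <- stage("fit", {
    p1 <- fit_pathway1(surveys$plots)
    responses <- build_biodiversity_responses(surveys$detections,
                                              surveys$pool,
                                              surveys$survey_locations)
    pts <- extract_stack(stack, surveys$survey_locations$x,
                         surveys$survey_locations$y,
                         surveys$survey_locations$location_id)
    names(pts)[1] <- "location_id"
    p2 <- fit_pathway2(responses, pts, config$models$p_enter)
    # conflict: risk rises near forest on cropland
    crop <- bundle$landcover$values == landcover_code("cropland")
    risk <- raster_grid(spec, matrix(
      stats::plogis(1 - stack$layers$dist_forest$values / 300),
      spec$n_rows))
    conflict <- simulate_conflict_events(
      risk, config$conflict$n_presence, config$conflict$n_absence,
      config$seeds$conflict, cropland_mask = crop)
    cpts <- extract_stack(stack, conflict$x, conflict$y)
    p3 <- fit_pathway3(conflict, cpts, config$models$p_enter)
    diag <- data.frame(
      metric_id = c(names(p2$models), "crop_raiding"),
      n = c(vapply(p2$models, function(m) m$n, 0), p3$n),
      n_selected = c(vapply(p2$models,
                            function(m) length(m$selection$selected), 0),
                     length(p3$selection$selected)),
      covariates = c(vapply(p2$models, function(m)
        paste(m$selection$selected, collapse = ";"), ""),
        paste(p3$selection$selected, collapse = ";")),
      moran_I = c(vapply(p2$models, function(m) m$moran$I, 0), p3$moran$I),
      moran_p = c(vapply(p2$models, function(m) m$moran$p_value, 0),
                  p3$moran$p_value))
    p <- file.path(out, "model_diagnostics.csv")
    utils::write.csv(diag, p, row.names = FALSE); add(p)
    list(p1 = p1, p2 = p2, p3 = p3, conflict = conflict)
  })
  scen <- stage("scenario", {
    cfg <- scenario_config(config$scenario$buffer_half_width,
                           config$scenario$attribute_imputation,
                           config$seeds$scenario)
    lc2 <- apply_riparian_buffer(bundle$landcover, bundle$rivers, cfg)
    st2 <- rebuild_scenario_stack(bundle, stack, lc2, cfg)
    add(write_raster(lc2, file.path(out, "scenario_landcover.asc")))
    audit <- conversion_audit(bundle$landcover, lc2)
    p <- file.path(out, "conversion_audit.csv")
    utils::write.csv(audit, p, row.names = FALSE); add(p)
    list(landcover = lc2, stack = st2)
  })
  maps <- stage("predict", {
    res <- list()
    for (m in names(fits$p2$models)) {
      mod <- fits$p2$models[[m]]$model
      pb <- predict_lda(mod, stack)
      ps <- predict_lda(mod, scen$stack)
      top <- mod$class_labels[length(mod$class_labels)]
      res[[m]] <- list(baseline = pb[[top]], scenario = ps[[top]])
      add(write_raster(pb[[top]],
                       file.path(out, paste0(m, "_baseline.asc"))))
      add(write_raster(ps[[top]],
                       file.path(out, paste0(m, "_scenario.asc"))))
    }
    rb <- predict_risk(fits$p3$model, stack)
    rs <- predict_risk(fits$p3$model, scen$stack)
    res$crop_raiding <- list(baseline = rb, scenario = rs)
    add(write_raster(rb, file.path(out, "crop_raiding_baseline.asc")))
    add(write_raster(rs, file.path(out, "crop_raiding_scenario.asc")))
    mask <- high_risk_change_mask(rb, rs)
    add(write_raster(mask, file.path(out, "high_risk_change.asc")))
    p <- file.path(out, "high_risk_change_legend.json")
    jsonlite::write_json(as.list(stats::setNames(
      seq_along(HIGH_RISK_CATEGORIES), HIGH_RISK_CATEGORIES)),
      p, auto_unbox = TRUE)
    add(p)
    res
  })
  stage("report", {
    plots <- surveys$plots
    units <- rbind(
      data.frame(unit_id = plots$plot_id, unit = "plot",
                 x = plots$x, y = plots$y),
      data.frame(unit_id = plots$habitat, unit = "habitat",
                 x = plots$x, y = plots$y))
    crop <- bundle$landcover$values == landcover_code("cropland")
    small <- crop & !bundle$plantation_mask
    ns <- config$sample_points$n_smallholder
    np <- config$sample_points$n_plantation
    if (sum(small) >= ns) {
      sp <- sample_random_points(small, ns, config$seeds$sample_points,
                                 spec)
      units <- rbind(units, data.frame(unit_id = "smallholder",
                                       unit = "production_system",
                                       x = sp$x, y = sp$y))
    }
    if (sum(bundle$plantation_mask) >= np) {
      pp <- sample_random_points(bundle$plantation_mask, np,
                                 config$seeds$sample_points + 1L, spec)
      units <- rbind(units, data.frame(unit_id = "plantation",
                                       unit = "production_system",
                                       x = pp$x, y = pp$y))
    }
    ct <- aggregate_change(maps, units)
    add(write_lollipop_csv(ct, file.path(out, "change_table.csv")))
    hs <- habitat_summary(plots$habitat, plots$canopy_closure)
    p <- file.path(out, "habitat_summary_canopy.csv")
    utils::write.csv(hs$summary, p, row.names = FALSE); add(p)
    hh <- simulate_households(config$households$n,
                              seed = config$seeds$households)
    p <- file.path(out, "households.csv")
    utils::write.csv(hh, p, row.names = FALSE); add(p)
    idx <- composite_index(normalize_indicators(hh))
    dm <- damage_effects_model(idx$index, hh$crop_damage_wildlife,
                               hh$crop_damage_elephant,
                               hh$respondent_gender, hh$village)
    pm <- perception_model(hh$perception, idx$index, hh$respondent_gender,
                           hh$village, hh$crop_damage_wildlife,
                           hh$crop_damage_elephant)
    p <- file.path(out, "wellbeing_model_comparison.csv")
    utils::write.csv(rbind(
      data.frame(family = "wellbeing_mixed", dm$aic),
      data.frame(family = "perception_ordinal", pm$aic)),
      p, row.names = FALSE)
    add(p)
    rd <- dimension_means_by_gender(idx, hh$respondent_gender)
    p <- file.path(out, "radar_dimension_means.csv")
    utils::write.csv(rd, p, row.names = FALSE); add(p)
    NULL
  })

  manifest <- list(
    package = "restoscape",
    version = as.character(utils::packageVersion("restoscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    # hash of the scientific configuration (output location excluded)
    config_hash = .md5_of_object(config[setdiff(names(config), "out_dir")]),
    outputs = lapply(stats::setNames(nm = paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  say(sprintf("done: %d outputs in %s", length(paths), out))
  invisible(manifest)
}

#' Command-line entry point
#'
#' `Rscript -e 'restoscape::pipeline_cli()' -- --stage all --seed 1
#'  --out DIR [--config config.json] [--buffer 60] [--impute mean]`
#'
#' @param args Argument vector (defaults to the command line).
#' @return The run manifest, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  take <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(take("--seed", "1"))
  out <- take("--out", tempfile("restoscape_run_"))
  cfg_path <- take("--config", NA)
  config <- if (!is.na(cfg_path))
    utils::modifyList(default_pipeline_config(seed, out_dir = out),
                      jsonlite::read_json(cfg_path, simplifyVector = TRUE))
  else default_pipeline_config(seed, out_dir = out)
  config$out_dir <- out
  config$scenario$buffer_half_width <-
    as.numeric(take("--buffer", config$scenario$buffer_half_width))
  config$scenario$attribute_imputation <-
    take("--impute", config$scenario$attribute_imputation)
  run_pipeline(config)
}
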
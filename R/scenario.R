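#' Riparian-restoration scenario configuration
#'
#' The scenario restores forest as linear structures of 60 m width on either
#' side of the river centrelines; `buffer_half_width` is that per-side
#' width in metres.
#'
#' @param buffer_half_width Metres (> 0, default 60).
#' @param attribute_imputation How restored pixels receive canopy closure
#'   and NDVI: `"mean"` (donor mean over current forest) or `"sample"`
#'   (seeded draws from the donor empirical distribution).
#' @param seed Seed used in sample mode.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(buffer_half_width = 60,
                            attribute_imputation = c("mean", "sample"),
                            seed = 1) {
  if (buffer_half_width <= 0)
    stop("`buffer_half_width` must be > 0", call. = FALSE)
  list(buffer_half_width = buffer_half_width,
       attribute_imputation = match.arg(attribute_imputation),
       seed = seed)
}

#' Convert riparian buffers to forest
#'
#' Every non-water, non-settlement pixel whose centre lies within
#' `buffer_half_width` metres of a river centreline becomes forest; all
#' other pixels are unchanged, so forest area never decreases.
#'
#' @param landcover Categorical [raster_grid()] over the five classes.
#' @param rivers Polyline list (river centrelines, metres).
#' @param config A [scenario_config()].
#' @return The scenario landcover [raster_grid()], with attribute
#'   `new_forest`: logical matrix of converted pixels.
#' @export
apply_riparian_buffer <- function(landcover, rivers,
                                  config = scenario_config()) {
  if (is.null(rivers) || length(rivers) == 0) {
    warning("empty river set: scenario landcover identical to baseline",
            call. = FALSE)
    out <- landcover
    attr(out, "new_forest") <- matrix(FALSE, landcover$spec$n_rows,
                                      landcover$spec$n_cols)
    return(out)
  }
  d <- distance_to_polylines(landcover$spec, rivers)
  lc <- landcover$values
  convertible <- !is.na(lc) &
    lc != landcover_code("water") & lc != landcover_code("settlement")
  new_forest <- convertible & d$values <= config$buffer_half_width &
    lc != landcover_code("forest")
  lc[convertible & d$values <= config$buffer_half_width] <-
    landcover_code("forest")
  out <- raster_grid(landcover$spec, lc, categories = landcover$categories)
  attr(out, "new_forest") <- new_forest
  out
}

#' Impute attributes of newly restored forest pixels
#'
#' New-forest pixels receive canopy closure (and, by the same mechanism,
#' NDVI) from the current-forest donor distribution: the donor mean in
#' `"mean"` mode, or seeded draws from the empirical donor values in
#' `"sample"` mode. All other pixels are unchanged.
#'
#' @param layer Continuous [raster_grid()] (e.g. canopy closure).
#' @param new_forest Logical matrix of restored pixels.
#' @param donor_values Numeric vector of the attribute over current forest
#'   pixels (>= 1 value).
#' @param config A [scenario_config()].
#' @return The updated [raster_grid()].
#' @export
impute_restored_attributes <- function(layer, new_forest, donor_values,
                                       config = scenario_config()) {
  if (!any(new_forest)) return(layer)
  donor_values <- donor_values[!is.na(donor_values)]
  if (length(donor_values) == 0)
    stop("no donor distribution: landscape has no current forest pixels",
         call. = FALSE)
  v <- layer$values
  k <- sum(new_forest)
  if (config$attribute_imputation == "mean") {
    v[new_forest] <- mean(donor_values)
  } else {
    v[new_forest] <- with_seed(config$seed,
                               sample(donor_values, k, replace = TRUE))
  }
  raster_grid(layer$spec, v)
}

#' Rebuild the covariate stack under the restoration scenario
#'
#' Recomputes the layers the scenario changes — distance to forest, percent
#' forest within 250 m, canopy closure and its focal statistics, and NDVI
#' and its focal statistics (restored pixels imputed from current-forest
#' donors) — and copies every other layer (distances to river, road,
#' settlement and plantation; population density; canopy height) from the
#' baseline stack.
#'
#' @param bundle The baseline landscape bundle.
#' @param baseline_stack [build_stack()] output for the bundle.
#' @param scenario_landcover [apply_riparian_buffer()] output (must carry
#'   the `new_forest` attribute).
#' @param config A [scenario_config()].
#' @return A `covariate_stack` with provenance `"scenario"`, plus attribute
#'   `new_forest`.
#' @export
rebuild_scenario_stack <- function(bundle, baseline_stack,
                                   scenario_landcover,
                                   config = scenario_config()) {
  if (!same_grid(bundle$landcover$spec, scenario_landcover$spec))
    stop("scenario landcover is not on the bundle's grid", call. = FALSE)
  new_forest <- attr(scenario_landcover, "new_forest")
  if (is.null(new_forest))
    new_forest <- scenario_landcover$values == landcover_code("forest") &
      bundle$landcover$values != landcover_code("forest")
  baseline_forest <- bundle$landcover$values == landcover_code("forest")

  cc <- impute_restored_attributes(
    bundle$canopy_closure, new_forest,
    bundle$canopy_closure$values[baseline_forest], config)
  nd <- impute_restored_attributes(
    bundle$ndvi, new_forest, bundle$ndvi$values[baseline_forest],
    config = within_seed_shift(config))

  layers <- baseline_stack$layers
  layers$canopy_closure <- cc
  layers$ndvi <- nd
  layers$dist_forest <- distance_to_class(scenario_landcover, "forest")
  layers$pct_forest_250 <- percent_class_in_window(scenario_landcover,
                                                   "forest", 250)
  layers$cc_mean_150 <- focal_stats(cc, 150, "mean")
  layers$cc_sd_150 <- focal_stats(cc, 150, "sd")
  layers$cc_mean_500 <- focal_stats(cc, 500, "mean")
  layers$cc_sd_500 <- focal_stats(cc, 500, "sd")
  layers$ndvi_mean_150 <- focal_stats(nd, 150, "mean")
  layers$ndvi_sd_150 <- focal_stats(nd, 150, "sd")
  layers$ndvi_mean_500 <- focal_stats(nd, 500, "mean")
  layers$ndvi_sd_500 <- focal_stats(nd, 500, "sd")

  out <- structure(list(spec = baseline_stack$spec, layers = layers,
                        provenance = "scenario"),
                   class = "covariate_stack")
  attr(out, "new_forest") <- new_forest
  out
}

# Derive an independent seed for the NDVI imputation so canopy closure and
# NDVI draws are not identical permutations in sample mode.
within_seed_shift <- function(config) {
  config$seed <- (config$seed + 104729L) %% .Machine$integer.max
  config
}

#' Per-class pixel conversion audit for a scenario
#'
#' @param baseline,scenario Categorical landcover rasters on one grid.
#' @return Data frame: from_class, to_class, n_pixels (only changed cells).
#' @export
conversion_audit <- function(baseline, scenario) {
  stopifnot_same_grid(baseline, scenario, "landcover rasters")
  changed <- which(baseline$values != scenario$values)
  if (length(changed) == 0)
    return(data.frame(from_class = character(0), to_class = character(0),
                      n_pixels = integer(0)))
  tab <- table(from = LANDCOVER_CLASSES[baseline$values[changed]],
               to = LANDCOVER_CLASSES[scenario$values[changed]])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  data.frame(from_class = df$from, to_class = df$to, n_pixels = df$Freq)
}
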
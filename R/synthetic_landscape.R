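#' Default synthetic-landscape configuration
#'
#' Class proportions describe a river-valley mosaic dominated by cropland
#' with forest blocks at the margins; canopy-closure distributions per class
#' use the field means/sds observed on the ground plots (forest 41.0 +/- 16.4
#' with a higher-closure woodland stratum folded in, grassland 8.2 +/- 13.9,
#' cropland 10.7 +/- 12.9). Two rivers traverse the extent east-west and six
#' villages anchor the settlement class.
#'
#' @param proportions Named numeric over the five landcover classes, summing
#'   to 1.
#' @param n_rivers Number of east-west rivers (>= 0).
#' @param n_villages Number of villages (>= 1).
#' @param plantation Logical: place an industrial-plantation block on
#'   cropland.
#' @return A config list for [generate_landscape()].
#' @export
default_landscape_config <- function(
    proportions = c(forest = 0.35, grassland = 0.20, cropland = 0.40,
                    water = 0.02, settlement = 0.03),
    n_rivers = 2, n_villages = 6, plantation = TRUE) {
  list(
    proportions = proportions,
    n_rivers = n_rivers,
    n_villages = n_villages,
    plantation = plantation,
    smooth_range_px = 6,
    canopy = list(  # mean, sd per class, truncated to [0, 100]
      forest = c(41.0, 16.4), woodland = c(43.5, 14.1),
      grassland = c(8.2, 13.9), cropland = c(10.7, 12.9),
      water = c(0, 0.5), settlement = c(2, 2)),
    woodland_fraction = 0.3,   # forest pixels drawn from the woodland stratum
    ndvi_base = c(forest = 0.75, grassland = 0.45, cropland = 0.50,
                  water = 0.05, settlement = 0.25),
    pop_peak = 25, pop_range_m = 500)
}

.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Edge-truncated running mean of a vector, half-width w (cells).
.running_mean <- function(v, w) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  hi <- pmin(n, seq_len(n) + w); lo <- pmax(1, seq_len(n) - w)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Smoothed Gaussian-like random field: white noise box-blurred three times
# along rows and columns (range_px controls patch size).
.smooth_field <- function(nr, nc, range_px) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  w <- max(1L, as.integer(range_px))
  for (i in 1:3) {
    m <- apply(m, 2, .running_mean, w = w)
    m <- t(apply(m, 1, .running_mean, w = w))
  }
  m
}

.random_river <- function(spec) {
  # eastward random walk spanning the full extent
  res <- spec$resolution
  x0 <- spec$origin_x
  x1 <- spec$origin_x + spec$n_cols * res
  y <- spec$origin_y - stats::runif(1, 0.2, 0.8) * spec$n_rows * res
  xs <- seq(x0, x1, by = 3 * res)
  if (xs[length(xs)] < x1) xs <- c(xs, x1)
  ys <- y + cumsum(c(0, stats::rnorm(length(xs) - 1, 0, 1.2 * res)))
  ylo <- spec$origin_y - (spec$n_rows - 0.5) * res
  yhi <- spec$origin_y - 0.5 * res
  cbind(x = xs, y = pmin(pmax(ys, ylo), yhi))
}

#' Generate a seeded synthetic landscape bundle
#'
#' Builds a five-class landcover mosaic (smoothed random field thresholded
#' at the requested class proportions, rivers burned in as water, villages
#' as settlement blocks), plus the continuous layers the covariate engine
#' consumes: canopy closure (%), NDVI, population density (people/ha) and
#' canopy height (m). Deterministic for fixed (spec, config, seed).
#'
#' @param spec A [grid_spec()].
#' @param config See [default_landscape_config()].
#' @param seed Integer seed.
#' @return A `landscape_bundle`: landcover, rivers, roads, villages,
#'   plantation_mask, canopy_closure, ndvi, pop_density, canopy_height,
#'   seed.
#' @export
generate_landscape <- function(spec, config = default_landscape_config(),
                               seed = 1) {
  p <- config$proportions
  if (is.null(names(p)) || !setequal(names(p), LANDCOVER_CLASSES))
    stop("configuration error: proportions must be named over the five ",
         "landcover classes", call. = FALSE)
  p <- p[LANDCOVER_CLASSES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("configuration error: class proportions must be >= 0 and sum to 1",
         call. = FALSE)
  if (config$n_rivers < 0) stop("configuration error: n_rivers < 0",
                                call. = FALSE)
  if (config$n_villages < 1) stop("configuration error: n_villages < 1",
                                  call. = FALSE)
  if (config$n_rivers > 0 && (spec$n_cols < 4 || spec$n_rows < 4))
    stop("capacity error: grid too small to place rivers", call. = FALSE)
  n_px <- spec$n_rows * spec$n_cols
  if (p[["settlement"]] > 0 && n_px < config$n_villages)
    stop("capacity error: grid too small for requested villages",
         call. = FALSE)

  with_seed(seed, {
    # --- field classes (forest / grassland / cropland) by quantile threshold
    fld <- .smooth_field(spec$n_rows, spec$n_cols, config$smooth_range_px)
    pf <- p[c("forest", "grassland", "cropland")]
    pf <- if (sum(pf) > 0) pf / sum(pf) else c(forest = 1, grassland = 0,
                                               cropland = 0)
    # high field values -> forest, low -> cropland
    q <- stats::quantile(fld, probs = cumsum(c(pf[["cropland"]],
                                               pf[["grassland"]])),
                         names = FALSE)
    lc <- matrix(landcover_code("cropland"), spec$n_rows, spec$n_cols)
    lc[fld >= q[1]] <- landcover_code("grassland")
    lc[fld >= q[2]] <- landcover_code("forest")

    # --- villages / settlement blocks
    villages <- NULL
    if (p[["settlement"]] > 0) {
      side <- max(1L, as.integer(round(sqrt(p[["settlement"]] * n_px /
                                              config$n_villages))))
      if (side > min(spec$n_rows, spec$n_cols))
        stop("capacity error: grid too small for requested villages",
             call. = FALSE)
      vr <- sample(seq_len(spec$n_rows - side + 1L), config$n_villages,
                   replace = TRUE)
      vc <- sample(seq_len(spec$n_cols - side + 1L), config$n_villages,
                   replace = TRUE)
      for (i in seq_len(config$n_villages))
        lc[vr[i]:(vr[i] + side - 1L), vc[i]:(vc[i] + side - 1L)] <-
          landcover_code("settlement")
      villages <- cbind(
        x = spec$origin_x + (vc + side / 2 - 0.5) * spec$resolution,
        y = spec$origin_y - (vr + side / 2 - 0.5) * spec$resolution)
      rownames(villages) <- paste0("village_", seq_len(config$n_villages))
    }

    # --- rivers burned in as water; one straight road along the top third
    rivers <- list()
    if (config$n_rivers > 0)
      rivers <- lapply(seq_len(config$n_rivers),
                       function(i) .random_river(spec))
    if (length(rivers) > 0) {
      rmask <- rasterize_polylines_mask(spec, rivers)
      lc[rmask] <- landcover_code("water")
    }
    ry <- spec$origin_y - 0.25 * spec$n_rows * spec$resolution
    roads <- list(cbind(
      x = c(spec$origin_x, spec$origin_x + spec$n_cols * spec$resolution),
      y = c(ry, ry)))

    # --- industrial plantation: one cropland block
    plantation_mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
    if (isTRUE(config$plantation)) {
      h <- max(1L, spec$n_rows %/% 5L); w <- max(1L, spec$n_cols %/% 5L)
      crop_idx <- which(lc == landcover_code("cropland"), arr.ind = TRUE)
      if (nrow(crop_idx) > 0) {
        anchor <- crop_idx[sample.int(nrow(crop_idx), 1), ]
        r0 <- min(anchor[1], spec$n_rows - h + 1L)
        c0 <- min(anchor[2], spec$n_cols - w + 1L)
        blk <- matrix(FALSE, spec$n_rows, spec$n_cols)
        blk[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
        plantation_mask <- blk & lc == landcover_code("cropland")
      }
    }

    # --- continuous layers
    cc <- matrix(0, spec$n_rows, spec$n_cols)
    cfg_c <- config$canopy
    for (cl in LANDCOVER_CLASSES) {
      idx <- which(lc == landcover_code(cl))
      if (length(idx) == 0) next
      if (cl == "forest") {
        wood <- stats::runif(length(idx)) < config$woodland_fraction
        cc[idx[!wood]] <- .rtruncnorm(sum(!wood), cfg_c$forest[1],
                                      cfg_c$forest[2])
        cc[idx[wood]] <- .rtruncnorm(sum(wood), cfg_c$woodland[1],
                                     cfg_c$woodland[2])
      } else {
        cc[idx] <- .rtruncnorm(length(idx), cfg_c[[cl]][1], cfg_c[[cl]][2])
      }
    }

    ndvi <- matrix(0, spec$n_rows, spec$n_cols)
    for (cl in LANDCOVER_CLASSES) {
      idx <- which(lc == landcover_code(cl))
      if (length(idx) == 0) next
      mu_cc <- if (cl == "forest") cfg_c$forest[1] else cfg_c[[cl]][1]
      ndvi[idx] <- config$ndvi_base[[cl]] + 0.003 * (cc[idx] - mu_cc) +
        stats::rnorm(length(idx), 0, 0.05)
    }
    ndvi <- pmin(pmax(ndvi, -1), 1)

    pop <- matrix(0.2, spec$n_rows, spec$n_cols)
    if (any(lc == landcover_code("settlement"))) {
      dset <- distance_to_class(raster_grid(spec, lc), "settlement")
      pop <- config$pop_peak * exp(-dset$values / config$pop_range_m) + 0.2
    }
    pop <- pop * matrix(exp(stats::rnorm(n_px, 0, 0.1)), spec$n_rows)

    height <- pmax(0.45 * cc + matrix(stats::rnorm(n_px, 0, 2), spec$n_rows),
                   0)

    structure(list(
      landcover = raster_grid(spec, lc, categories = LANDCOVER_CLASSES),
      rivers = rivers, roads = roads, villages = villages,
      plantation_mask = plantation_mask,
      canopy_closure = raster_grid(spec, cc),
      ndvi = raster_grid(spec, ndvi),
      pop_density = raster_grid(spec, pop),
      canopy_height = raster_grid(spec, height),
      config = config, seed = seed), class = "landscape_bundle")
  })
}

#' @export
print.landscape_bundle <- function(x, ...) {
  tab <- table(factor(LANDCOVER_CLASSES[x$landcover$values],
                      levels = LANDCOVER_CLASSES))
  cat(sprintf("<landscape_bundle> %d x %d @ %g m, seed %d\n",
              x$landcover$spec$n_rows, x$landcover$spec$n_cols,
              x$landcover$spec$resolution, x$seed))
  print(tab)
  invisible(x)
}

#' Generate a synthetic species-trait pool
#'
#' Diet fractions over \{invertebrate, vertebrate, plant_seed, other\} sum
#' to 1; a configurable fraction of species has a dominant (> 50%) diet item
#' and a configurable fraction carries a threatened status (VU/EN/CR).
#'
#' @param n_birds,n_mammals Species counts (>= 0, together >= 1).
#' @param seed Integer seed.
#' @param p_dominant Fraction of species with a dominant diet item.
#' @param p_threatened Fraction with status in \{VU, EN, CR\}.
#' @return Data frame: species_id, taxon, diet_invertebrate,
#'   diet_vertebrate, diet_plant_seed, diet_other, threat_status.
#' @export
generate_species_pool <- function(n_birds, n_mammals, seed = 1,
                                  p_dominant = 0.75, p_threatened = 0.2) {
  if (n_birds < 0 || n_mammals < 0)
    stop("argument error: species counts must be >= 0", call. = FALSE)
  n <- n_birds + n_mammals
  if (n < 1) stop("argument error: need at least one species", call. = FALSE)
  with_seed(seed, {
    taxon <- c(rep("bird", n_birds), rep("mammal", n_mammals))
    diets <- matrix(0, n, 4,
                    dimnames = list(NULL, c("invertebrate", "vertebrate",
                                            "plant_seed", "other")))
    dominant <- stats::runif(n) < p_dominant
    for (i in seq_len(n)) {
      g <- stats::rgamma(4, shape = 1)
      fr <- g / sum(g)
      if (dominant[i]) {
        j <- sample.int(3, 1)  # dominant item among the three guild diets
        d <- stats::runif(1, 0.55, 0.95)
        rest <- g[-j] / sum(g[-j]) * (1 - d)
        fr <- numeric(4); fr[j] <- d; fr[-j] <- rest
      }
      diets[i, ] <- fr
    }
    threatened <- stats::runif(n) < p_threatened
    status <- ifelse(threatened,
                     sample(c("VU", "EN", "CR"), n, replace = TRUE),
                     sample(c("LC", "NT", "DD"), n, replace = TRUE,
                            prob = c(0.8, 0.1, 0.1)))
    data.frame(
      species_id = sprintf("%s_%03d", taxon, stats::ave(seq_len(n), taxon,
                                                        FUN = seq_along)),
      taxon = taxon,
      diet_invertebrate = diets[, 1], diet_vertebrate = diets[, 2],
      diet_plant_seed = diets[, 3], diet_other = diets[, 4],
      threat_status = status)
  })
}

#' Default response parameters for the survey simulator
#'
#' Microclimate follows the field-calibrated linear model: ground surface
#' temperature declines by 0.117 degC per percent canopy closure from a
#' 36.5 degC open-ground intercept, with residual sd 3.76 degC (the sd that
#' reproduces the reported 22.5% deviance explained when canopy closure is
#' spread over 0-60%).
#' @return Named list of generator coefficients.
#' @export
default_response_params <- function() {
  list(
    t_ground = c(intercept = 36.5, slope = -0.117, sd = 3.76),
    t_leaf = c(intercept = 33.0, scale = -0.55, sd = 2.2),  # a + scale*sqrt(cc)
    fluorescence = c(intercept = 36.0, slope = 0.10, sd = 4.0),
    yield = list(okra = c(intercept = 20, slope = 0.0, sd = 4),
                 sugarcane = c(intercept = 55, slope = 0.0, sd = 10),
                 maize = c(intercept = 30, slope = 0.4, sd = 5)),
    richness = list(
      mammal = c(log_lambda0 = log(4), sep = 1.0),   # loads on pct_forest_250
      bird = c(log_lambda0 = log(8), sep = -0.6)))
}

.sample_class_cells <- function(lc_values, code, n) {
  idx <- which(lc_values == code)
  if (length(idx) < n)
    stop(sprintf("capacity error: only %d pixels of the requested class",
                 length(idx)), call. = FALSE)
  idx[sample.int(length(idx), n)]
}

#' Simulate plot measurements and species detections
#'
#' Ecological plots are placed per habitat (woodland plots drawn from the
#' upper canopy-closure stratum of forest); microclimate responses are
#' generated from the linear/smooth models in `response_params`, yields only
#' on cropland plots. Species detections at survey points have per-taxon
#' richness drawn Poisson with log-intensity linear in a landscape covariate
#' (mammals: percent forest within 250 m, positive; birds: negative), so a
#' zero separation parameter removes all covariate dependence.
#'
#' @param bundle A landscape bundle.
#' @param stack Covariate stack built on the bundle.
#' @param pool Species pool from [generate_species_pool()].
#' @param response_params See [default_response_params()].
#' @param seed Integer seed.
#' @param n_plots Named plot counts per habitat (default mirrors the 72
#'   field plots: forest 12, woodland 5, grassland 7, cropland 48).
#' @param survey_xy Optional n x 2 matrix of detection-survey coordinates;
#'   defaults to `n_survey` random non-water pixels. Out-of-extent
#'   coordinates raise a bounds error.
#' @param n_survey Number of random survey points when `survey_xy` is NULL.
#' @return List with `plots` (plot table incl. microclimate and yield) and
#'   `detections` (long table location x species).
#' @export
simulate_point_surveys <- function(bundle, stack, pool,
                                   response_params = default_response_params(),
                                   seed = 1,
                                   n_plots = c(forest = 12, woodland = 5,
                                               grassland = 7, cropland = 48),
                                   survey_xy = NULL, n_survey = 120) {
  spec <- bundle$landcover$spec
  lc <- bundle$landcover$values
  if (!is.null(survey_xy))
    cell_from_xy(spec, survey_xy[, 1], survey_xy[, 2])  # bounds check
  with_seed(seed, {
    # --- plots ---------------------------------------------------------
    cells <- integer(0); habitat <- character(0)
    fcode <- landcover_code("forest")
    for (h in names(n_plots)) {
      n <- n_plots[[h]]
      if (n == 0) next
      if (h %in% c("forest", "woodland")) {
        idx <- which(lc == fcode)
        if (length(idx) == 0)
          stop("capacity error: no forest pixels for forest/woodland plots",
               call. = FALSE)
        cc <- bundle$canopy_closure$values[idx]
        med <- stats::median(cc)
        pickable <- if (h == "woodland") idx[cc >= med] else idx[cc < med]
        if (length(pickable) < n) pickable <- idx
        cells <- c(cells, pickable[sample.int(length(pickable), n)])
      } else {
        cells <- c(cells, .sample_class_cells(lc, landcover_code(h), n))
      }
      habitat <- c(habitat, rep(h, n))
    }
    rc <- arrayInd(cells, dim(lc))
    xy <- pixel_centres(spec, rc[, 1], rc[, 2])
    cc <- bundle$canopy_closure$values[cells]
    np <- length(cells)
    pr <- response_params
    plots <- data.frame(
      plot_id = sprintf("plot_%03d", seq_len(np)),
      x = xy[, 1], y = xy[, 2], habitat = habitat, canopy_closure = cc,
      t_ground = pr$t_ground[["intercept"]] + pr$t_ground[["slope"]] * cc +
        stats::rnorm(np, 0, pr$t_ground[["sd"]]),
      t_leaf = pr$t_leaf[["intercept"]] +
        pr$t_leaf[["scale"]] * sqrt(cc) +
        stats::rnorm(np, 0, pr$t_leaf[["sd"]]),
      fluorescence = pr$fluorescence[["intercept"]] +
        pr$fluorescence[["slope"]] * cc +
        stats::rnorm(np, 0, pr$fluorescence[["sd"]]),
      crop_type = NA_character_, yield = NA_real_)
    crop_rows <- which(plots$habitat == "cropland")
    if (length(crop_rows) > 0) {
      types <- names(pr$yield)
      plots$crop_type[crop_rows] <- sample(types, length(crop_rows),
                                           replace = TRUE)
      for (ct in types) {
        rows <- crop_rows[plots$crop_type[crop_rows] == ct]
        if (length(rows) == 0) next
        cf <- pr$yield[[ct]]
        plots$yield[rows] <- pmax(
          cf[["intercept"]] + cf[["slope"]] * plots$canopy_closure[rows] +
            stats::rnorm(length(rows), 0, cf[["sd"]]), 0)
      }
    }

    # --- detections ----------------------------------------------------
    if (is.null(survey_xy)) {
      ok <- which(lc != landcover_code("water"))
      sv <- ok[sample.int(length(ok), min(n_survey, length(ok)))]
      src <- arrayInd(sv, dim(lc))
      survey_xy <- pixel_centres(spec, src[, 1], src[, 2])
    }
    pf <- extract_at(stack$layers$pct_forest_250, survey_xy[, 1],
                     survey_xy[, 2])
    z <- if (stats::sd(pf) > 0) (pf - mean(pf)) / stats::sd(pf) else pf * 0
    det <- list()
    for (tx in c("bird", "mammal")) {
      sp <- pool[pool$taxon == tx, , drop = FALSE]
      if (nrow(sp) == 0) next
      cf <- response_params$richness[[tx]]
      lam <- exp(cf[["log_lambda0"]] + cf[["sep"]] * z)
      counts <- pmin(stats::rpois(length(lam), lam), nrow(sp))
      for (i in seq_along(counts)) {
        if (counts[i] == 0) next
        picked <- sp$species_id[sample.int(nrow(sp), counts[i])]
        det[[length(det) + 1]] <- data.frame(
          location_id = sprintf("loc_%03d", i),
          x = unname(survey_xy[i, 1]), y = unname(survey_xy[i, 2]),
          species_id = picked, taxon = tx)
      }
    }
    detections <- if (length(det)) do.call(rbind, det) else
      data.frame(location_id = character(0), x = numeric(0), y = numeric(0),
                 species_id = character(0), taxon = character(0))
    locs <- data.frame(location_id = sprintf("loc_%03d",
                                             seq_len(nrow(survey_xy))),
                       x = survey_xy[, 1], y = survey_xy[, 2])
    list(plots = plots, detections = detections, survey_locations = locs)
  })
}

#' Simulate crop-raiding presence/absence events
#'
#' Presence points are sampled (with replacement) over eligible cropland
#' pixels with probability proportional to the risk surface; absence points
#' proportional to 1 - risk. Defaults mirror the monitored incident counts
#' (308 presence, 97 absence).
#'
#' @param risk_surface [raster_grid()] of event probability in \[0, 1\].
#' @param n_presence,n_absence Point counts.
#' @param seed Integer seed.
#' @param cropland_mask Optional logical matrix restricting eligible pixels;
#'   defaults to all non-NA risk pixels.
#' @return Data frame: x, y, outcome ("presence"/"absence"), risk.
#' @export
simulate_conflict_events <- function(risk_surface, n_presence = 308,
                                     n_absence = 97, seed = 1,
                                     cropland_mask = NULL) {
  v <- risk_surface$values
  if (is.null(cropland_mask)) cropland_mask <- !is.na(v)
  eligible <- which(cropland_mask & !is.na(v))
  if (any(v[eligible] < 0 | v[eligible] > 1))
    stop("risk surface values must lie in [0, 1]", call. = FALSE)
  if (length(eligible) < max(n_presence, n_absence))
    stop(sprintf(
      "capacity error: %d eligible cropland pixels for %d requested points",
      length(eligible), max(n_presence, n_absence)), call. = FALSE)
  with_seed(seed, {
    draw <- function(n, w) {
      if (sum(w) == 0) w <- rep(1, length(w))  # flat fallback
      eligible[sample.int(length(eligible), n, replace = TRUE, prob = w)]
    }
    cells <- c(draw(n_presence, v[eligible]),
               draw(n_absence, 1 - v[eligible]))
    rc <- arrayInd(cells, dim(v))
    xy <- pixel_centres(risk_surface$spec, rc[, 1], rc[, 2])
    data.frame(x = xy[, 1], y = xy[, 2],
               outcome = rep(c("presence", "absence"),
                             c(n_presence, n_absence)),
               risk = v[cells])
  })
}

#' Default generating coefficients for the household simulator
#'
#' The perception submodel is a cumulative-logit (proportional-odds) model
#' on the computed composite wellbeing index with the reported coefficients
#' (wellbeing +2.43, woman -0.51) and fixed thresholds (-1, 0, 1, 2) chosen
#' once to populate all five response categories.
#' @param n_villages Number of villages (wellbeing means are spread over
#'   villages).
#' @return Named list of generator coefficients.
#' @export
default_household_coef <- function(n_villages = 6) {
  list(
    wellbeing = list(kind = "village",
                     means = seq(0.35, 0.65, length.out = n_villages),
                     sd = 0.12),
    indicator_sd = 0.18,
    gender_wellbeing = -0.03,
    p_damage_wildlife = 0.30, p_damage_elephant = 0.15,
    thresholds = c(-1, 0, 1, 2),
    beta_wellbeing = 2.43, beta_gender = -0.51,
    beta_damage_wildlife = 0, beta_damage_elephant = 0,
    village_perception = rep(0, n_villages))
}

#' Simulate a household wellbeing survey
#'
#' Generates 20 raw indicator values per household around a latent household
#' wellbeing level (village mean + gender shift + noise, or Uniform(0,1)
#' when `coef$wellbeing$kind == "uniform"`), derives the composite index
#' with the shipped schema, and draws the ordinal perception score (0-4)
#' from the proportional-odds model in `coef`.
#'
#' @param n Number of households (>= 1).
#' @param villages Character vector of village names (>= 1).
#' @param coef See [default_household_coef()].
#' @param seed Integer seed.
#' @param schema Indicator schema, see [default_indicator_schema()].
#' @return Data frame with household_id, village, respondent_gender, the 20
#'   indicator columns, damage flags, perception, and the generating latent
#'   index as attribute-free column `wellbeing_index` (the computed
#'   composite, for convenience).
#' @export
simulate_households <- function(n = 461,
                                villages = paste0("village_", 1:6),
                                coef = default_household_coef(
                                  length(villages)),
                                seed = 1,
                                schema = default_indicator_schema()) {
  if (n < 1) stop("argument error: n must be >= 1", call. = FALSE)
  if (length(villages) < 1)
    stop("argument error: empty village list", call. = FALSE)
  with_seed(seed, {
    village <- sample(villages, n, replace = TRUE)
    gender <- sample(c("man", "woman"), n, replace = TRUE)
    if (identical(coef$wellbeing$kind, "uniform")) {
      w <- stats::runif(n)
    } else {
      mu <- coef$wellbeing$means[match(village, villages)]
      w <- stats::rnorm(n, mu, coef$wellbeing$sd)
    }
    w <- w + coef$gender_wellbeing * (gender == "woman")
    w <- pmin(pmax(w, 0.01), 0.99)

    rec <- data.frame(household_id = sprintf("hh_%04d", seq_len(n)),
                      village = village, respondent_gender = gender)
    for (i in seq_len(nrow(schema))) {
      norm <- pmin(pmax(w + stats::rnorm(n, 0, coef$indicator_sd), 0), 1)
      if (!schema$higher_is_better[i]) norm <- 1 - norm
      rec[[schema$name[i]]] <- schema$min[i] +
        norm * (schema$max[i] - schema$min[i])
    }
    rec$crop_damage_wildlife <- as.integer(stats::runif(n) <
                                             coef$p_damage_wildlife)
    rec$crop_damage_elephant <- as.integer(stats::runif(n) <
                                             coef$p_damage_elephant)

    idx <- composite_index(normalize_indicators(rec, schema), schema)$index
    eta <- coef$beta_wellbeing * idx +
      coef$beta_gender * (gender == "woman") +
      coef$village_perception[match(village, villages)] +
      coef$beta_damage_wildlife * rec$crop_damage_wildlife +
      coef$beta_damage_elephant * rec$crop_damage_elephant
    th <- coef$thresholds
    cum <- outer(eta, th, function(e, t) stats::plogis(t - e)) # P(Y <= k)
    u <- stats::runif(n)
    rec$perception <- rowSums(u > cum) # number of cut-points passed, 0..K-1
    rec$wellbeing_index <- idx
    rec
  })
}
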
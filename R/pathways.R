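VALID_THREAT_CODES <- c("LC", "NT", "VU", "EN", "CR", "DD")

#' Classify a species into a diet guild
#'
#' A species is assigned the guild of its dominant diet item — the item
#' making up strictly more than 50% of the diet — among invertebrates,
#' vertebrates, and plants/seeds; `"none"` when no item exceeds 50% (or the
#' residual "other" category dominates).
#'
#' @param trait A one-row data frame or list with diet_invertebrate,
#'   diet_vertebrate, diet_plant_seed, diet_other.
#' @return One of "invertebrate", "vertebrate", "plant_seed", "none".
#' @export
classify_guild <- function(trait) {
  grab <- function(f) if (is.null(trait[[f]])) 0 else as.numeric(trait[[f]])
  fr <- c(invertebrate = grab("diet_invertebrate"),
          vertebrate = grab("diet_vertebrate"),
          plant_seed = grab("diet_plant_seed"),
          other = grab("diet_other"))
  if (abs(sum(fr) - 1) > 1e-9)
    stop("validation error: diet fractions must sum to 1", call. = FALSE)
  guilds <- fr[c("invertebrate", "vertebrate", "plant_seed")]
  if (max(guilds) > 0.5) names(which.max(guilds)) else "none"
}

#' Flag threatened IUCN status
#'
#' TRUE iff status is vulnerable (VU), endangered (EN) or critically
#' endangered (CR).
#'
#' @param status One of LC, NT, VU, EN, CR, DD (vectorised).
#' @return Logical vector.
#' @export
flag_threatened <- function(status) {
  if (!all(status %in% VALID_THREAT_CODES))
    stop("validation error: unknown threat status code(s): ",
         paste(setdiff(status, VALID_THREAT_CODES), collapse = ", "),
         call. = FALSE)
  status %in% c("VU", "EN", "CR")
}

#' Split species counts into richness classes
#'
#' Quantile (median or tertile) split of the training counts into low/high
#' or low/medium/high, with ties assigned to the lower class. Thresholds are
#' returned so the same cut-points can be reused at prediction time.
#'
#' @param counts Per-location species counts.
#' @param n_classes 2 or 3.
#' @return List: `labels` (ordered factor) and `thresholds`.
#' @export
richness_classes <- function(counts, n_classes = 3) {
  if (!n_classes %in% c(2, 3)) stop("n_classes must be 2 or 3",
                                    call. = FALSE)
  if (length(unique(counts)) < n_classes)
    stop("degenerate counts: fewer distinct values than classes",
         call. = FALSE)
  probs <- if (n_classes == 2) 0.5 else c(1 / 3, 2 / 3)
  th <- stats::quantile(counts, probs, names = FALSE)
  lev <- if (n_classes == 2) c("low", "high") else c("low", "medium", "high")
  lab <- rep(lev[n_classes], length(counts))
  for (k in rev(seq_along(th))) lab[counts <= th[k]] <- lev[k]
  list(labels = factor(lab, levels = lev, ordered = TRUE), thresholds = th)
}

.order_labels <- function(labels) {
  u <- unique(as.character(labels))
  for (lev in list(c("low", "medium", "high"), c("low", "high"),
                   c("absence", "presence"), c("absent", "present")))
    if (setequal(u, lev)) return(factor(labels, levels = lev))
  factor(labels)
}

#' Pathway 1: microclimate and yield responses to canopy closure
#'
#' Fits each response (ground temperature, leaf temperature, leaf
#' fluorescence; crop yield per crop type) on canopy closure, as both a
#' straight line and a regression-spline smooth, and keeps the simpler model
#' unless the nested F test rejects it.
#'
#' @param plots Plot table with canopy_closure, t_ground, t_leaf,
#'   fluorescence and (for cropland plots) crop_type, yield.
#' @param alpha Model-choice significance level.
#' @return List with one entry per response: chosen, fit, F, p_value;
#'   `yields` holds per-crop fits; crops with too few plots are skipped and
#'   listed in `skipped`.
#' @export
fit_pathway1 <- function(plots, alpha = 0.05) {
  needed <- c("canopy_closure", "t_ground", "t_leaf", "fluorescence")
  missing <- setdiff(needed, names(plots))
  if (length(missing))
    stop("schema error: plot table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fit_one <- function(x, y) {
    g <- fit_glm_gaussian(x, y)
    if (length(x) > 5) {
      s <- fit_smooth(x, y, df = 4)
      compare_models(g, s, alpha)
    } else list(chosen = "glm", fit = g, F = NA_real_, p_value = NA_real_)
  }
  out <- list()
  for (resp in c("t_ground", "t_leaf", "fluorescence"))
    out[[resp]] <- fit_one(plots$canopy_closure, plots[[resp]])
  out$yields <- list(); out$skipped <- character(0)
  if ("yield" %in% names(plots)) {
    crop <- plots[!is.na(plots$yield) & !is.na(plots$crop_type), ,
                  drop = FALSE]
    for (ct in unique(crop$crop_type)) {
      sub <- crop[crop$crop_type == ct, ]
      if (nrow(sub) < 3 || stats::sd(sub$canopy_closure) == 0) {
        message("skipping yield fit for crop type '", ct,
                "': too few plots or no canopy variation")
        out$skipped <- c(out$skipped, ct)
        next
      }
      out$yields[[ct]] <- fit_one(sub$canopy_closure, sub$yield)
    }
  }
  out
}

# Expected-class-score residual of an LDA fit: observed score (classes
# scored 1..K in declared order) minus the posterior-weighted score.
.lda_score_residuals <- function(model, X, labels) {
  post <- predict_lda(model, X)
  s_obs <- match(as.character(labels), model$class_labels)
  s_obs - as.numeric(post %*% seq_along(model$class_labels))
}

#' Pathway 2: landscape-configuration models of biodiversity metrics
#'
#' Per biodiversity metric: collinearity filter on the candidate covariates,
#' greedy Wilks'-Lambda forward selection, LDA fit on the retained
#' covariates, and Moran's I on the expected-class-score residuals as the
#' spatial-autocorrelation diagnostic. Metrics with a single observed class
#' (or no covariate passing selection) are reported as skipped rather than
#' fit.
#'
#' @param responses Data frame: location_id, metric_id, label.
#' @param stack_at_points Data frame: location_id, x, y, one column per
#'   covariate.
#' @param p_enter Forward-selection entry threshold.
#' @return List of per-metric results (`models`) plus `skipped`.
#' @export
fit_pathway2 <- function(responses, stack_at_points, p_enter = 0.05) {
  cov_names <- setdiff(names(stack_at_points), c("location_id", "x", "y",
                                                 "point_id"))
  models <- list(); skipped <- list()
  for (m in unique(responses$metric_id)) {
    sub <- responses[responses$metric_id == m, ]
    dat <- merge(sub, stack_at_points, by = "location_id")
    labs <- .order_labels(dat$label)
    if (length(unique(labs)) < 2) {
      skipped[[m]] <- "single observed class"
      next
    }
    kept <- suppressWarnings(
      correlation_filter(dat[, cov_names, drop = FALSE]))
    sel <- greedy_wilks_forward(dat[, kept, drop = FALSE], labs, p_enter)
    if (length(sel$selected) == 0) {
      skipped[[m]] <- "no covariate passed forward selection"
      next
    }
    model <- fit_lda(dat[, sel$selected, drop = FALSE], labs)
    res <- .lda_score_residuals(model, dat[, sel$selected, drop = FALSE],
                                labs)
    moran <- tryCatch(
      morans_i(res, dat[, c("x", "y")]),
      error = function(e) list(I = NA_real_, expected = NA_real_,
                               sd = NA_real_, z = NA_real_,
                               p_value = NA_real_))
    models[[m]] <- list(metric_id = m, model = model,
                        selection = sel, moran = moran, n = nrow(dat))
  }
  list(models = models, skipped = skipped)
}

#' Predict biodiversity probability surfaces from a pathway-2 model
#'
#' @param model An `lda_model` (e.g. from [fit_pathway2()]).
#' @param stack Baseline or scenario `covariate_stack`.
#' @return Named list of per-class probability rasters (summing to 1 per
#'   pixel).
#' @export
map_predictions <- function(model, stack) predict_lda(model, stack)

#' Pathway 3: crop-raiding risk model
#'
#' LDA of conflict presence/absence on landscape-configuration covariates
#' (collinearity filter + greedy Wilks forward selection), yielding a
#' presence-posterior risk surface in \[0, 1\] when predicted over a stack.
#'
#' @param conflict Data frame: x, y, outcome ("presence"/"absence").
#' @param stack_at_points Covariates at the conflict points (rows aligned
#'   with `conflict`).
#' @param p_enter Forward-selection entry threshold.
#' @return List: model, selection, moran, n.
#' @export
fit_pathway3 <- function(conflict, stack_at_points, p_enter = 0.05) {
  labs <- .order_labels(conflict$outcome)
  if (length(unique(labs)) < 2)
    stop("conflict dataset has a single outcome class", call. = FALSE)
  cov_names <- setdiff(names(stack_at_points), c("location_id", "x", "y",
                                                 "point_id"))
  kept <- suppressWarnings(
    correlation_filter(stack_at_points[, cov_names, drop = FALSE]))
  sel <- greedy_wilks_forward(stack_at_points[, kept, drop = FALSE], labs,
                              p_enter)
  use <- if (length(sel$selected) > 0) sel$selected else kept[1]
  model <- fit_lda(stack_at_points[, use, drop = FALSE], labs)
  res <- .lda_score_residuals(model, stack_at_points[, use, drop = FALSE],
                              labs)
  moran <- tryCatch(morans_i(res, conflict[, c("x", "y")]),
                    error = function(e) list(I = NA_real_, p_value = NA_real_))
  list(model = model, selection = sel, moran = moran, n = nrow(conflict))
}

#' Crop-raiding risk surface from a pathway-3 model
#'
#' @param model The pathway-3 `lda_model`.
#' @param stack A `covariate_stack`.
#' @return [raster_grid()] of presence posterior probability in \[0, 1\]
#'   (landscape-wide; mask to cropland downstream for reporting).
#' @export
predict_risk <- function(model, stack) {
  post <- predict_lda(model, stack)
  post[["presence"]]
}

#' Build biodiversity response tables from detections
#'
#' Pools detections over visits per location and taxon, derives richness
#' classes (tertiles for all-species richness, medians for guild subsets)
#' and threatened presence/absence, mirroring the indicator set: high
#' species number, threatened presence, and high numbers of plant/seed
#' eaters per taxon.
#'
#' @param detections Long table: location_id, species_id, taxon.
#' @param pool Species pool with traits.
#' @param locations Data frame location_id, x, y of all surveyed locations
#'   (locations without detections count as richness 0).
#' @return Data frame: location_id, metric_id, label.
#' @export
build_biodiversity_responses <- function(detections, pool, locations) {
  pool$guild <- vapply(seq_len(nrow(pool)),
                       function(i) classify_guild(pool[i, ]), "")
  pool$threatened <- flag_threatened(pool$threat_status)
  det <- merge(detections, pool[, c("species_id", "guild", "threatened")],
               by = "species_id")
  out <- list()
  for (tx in unique(pool$taxon)) {
    d <- det[det$taxon == tx, ]
    cnt <- table(factor(d$location_id, levels = locations$location_id))
    # all-species richness: low/medium/high
    rc <- tryCatch(richness_classes(as.numeric(cnt), 3),
                   error = function(e) NULL)
    if (!is.null(rc))
      out[[length(out) + 1]] <- data.frame(
        location_id = locations$location_id,
        metric_id = paste0(tx, "s_high"),
        label = as.character(rc$labels))
    # plant/seed-eating richness: low/high
    dh <- d[d$guild == "plant_seed", ]
    cnt2 <- table(factor(dh$location_id, levels = locations$location_id))
    rc2 <- tryCatch(richness_classes(as.numeric(cnt2), 2),
                    error = function(e) NULL)
    if (!is.null(rc2))
      out[[length(out) + 1]] <- data.frame(
        location_id = locations$location_id,
        metric_id = paste0(tx, "s_HSP"),
        label = as.character(rc2$labels))
    # threatened presence/absence
    dt <- d[d$threatened, ]
    pres <- locations$location_id %in% dt$location_id
    out[[length(out) + 1]] <- data.frame(
      location_id = locations$location_id,
      metric_id = paste0(tx, "s_threatened"),
      label = ifelse(pres, "present", "absent"))
  }
  do.call(rbind, out)
}
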
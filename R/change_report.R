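#' Pixelwise scenario-minus-baseline delta raster
#'
#' @param baseline,scenario Probability (or other) rasters on one grid;
#'   nodata propagates.
#' @return [raster_grid()] of deltas.
#' @export
delta_raster <- function(baseline, scenario) {
  stopifnot_same_grid(baseline, scenario)
  raster_grid(baseline$spec, scenario$values - baseline$values)
}

#' High-risk change mask category labels (codes 1-4)
#' @export
HIGH_RISK_CATEGORIES <- c("stable_low", "new_high", "lost_high",
                          "stable_high")

#' High-risk change mask
#'
#' Categorises every valid pixel by whether predicted risk exceeds the
#' threshold (strictly) before and after the scenario: stable_low,
#' new_high, lost_high, stable_high. The boundary value itself is "low".
#'
#' @param baseline,scenario Probability rasters on one grid.
#' @param threshold Risk threshold (default 0.5).
#' @return Categorical [raster_grid()] (codes 1-4 with category labels).
#' @export
high_risk_change_mask <- function(baseline, scenario, threshold = 0.5) {
  stopifnot_same_grid(baseline, scenario)
  b <- baseline$values > threshold
  s <- scenario$values > threshold
  # stable_low = 1, new_high = 2, lost_high = 3, stable_high = 4
  code <- matrix(1L, nrow(b), ncol(b))
  code[s & !b] <- 2L
  code[b & !s] <- 3L
  code[b & s] <- 4L
  code[is.na(baseline$values) | is.na(scenario$values)] <- NA_integer_
  raster_grid(baseline$spec, code, categories = HIGH_RISK_CATEGORIES)
}

#' Sample random pixel-centre points under a mask
#'
#' Uniform sampling without replacement over the TRUE pixels of a mask
#' (e.g. 50 points in smallholder-farmed land and 50 in the commercial
#' plantation).
#'
#' @param mask Logical matrix or [raster_grid()] of eligibility.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param spec [grid_spec()]; required when `mask` is a bare matrix.
#' @return Data frame: x, y, row, col.
#' @export
sample_random_points <- function(mask, n, seed = 1, spec = NULL) {
  if (inherits(mask, "raster_grid")) {
    spec <- mask$spec
    mask <- !is.na(mask$values) & mask$values != 0
  }
  if (is.null(spec)) stop("`spec` required with a bare mask", call. = FALSE)
  idx <- which(mask)
  if (length(idx) < n)
    stop(sprintf("capacity error: mask has %d pixels for %d points",
                 length(idx), n), call. = FALSE)
  cells <- with_seed(seed, idx[sample.int(length(idx), n)])
  rc <- arrayInd(cells, dim(mask))
  xy <- pixel_centres(spec, rc[, 1], rc[, 2])
  data.frame(x = xy[, 1], y = xy[, 2], row = rc[, 1], col = rc[, 2])
}

#' Aggregate baseline/scenario change over reporting units
#'
#' Extracts each metric's baseline and scenario values at member points and
#' averages per unit (plot, habitat, production system); unit value =
#' arithmetic mean over members, and the aggregated delta equals the mean of
#' member deltas. Empty units are reported with NA, not dropped.
#'
#' @param metric_rasters Named list; each element is
#'   `list(baseline = raster, scenario = raster)`.
#' @param units Data frame: unit_id, unit (type label, e.g. "plot",
#'   "habitat", "production_system"), x, y. Several rows may share a
#'   unit_id (members).
#' @return A `change_table` data frame: metric_id, unit, unit_id,
#'   baseline_value, scenario_value, delta, n_members.
#' @export
aggregate_change <- function(metric_rasters, units) {
  out <- list()
  for (m in names(metric_rasters)) {
    b <- metric_rasters[[m]]$baseline
    s <- metric_rasters[[m]]$scenario
    stopifnot_same_grid(b, s)
    key <- unique(units[, c("unit_id", "unit")])
    for (i in seq_len(nrow(key))) {
      mem <- units[units$unit_id == key$unit_id[i] &
                     units$unit == key$unit[i], , drop = FALSE]
      if (nrow(mem) == 0) {
        bv <- sv <- NA_real_
      } else {
        bv <- mean(extract_at(b, mem$x, mem$y))
        sv <- mean(extract_at(s, mem$x, mem$y))
      }
      out[[length(out) + 1]] <- data.frame(
        metric_id = m, unit = key$unit[i], unit_id = key$unit_id[i],
        baseline_value = bv, scenario_value = sv, delta = sv - bv,
        n_members = nrow(mem))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("change_table", class(res))
  res
}

#' Write a change table in lollipop-plot format
#'
#' @param change_table [aggregate_change()] output.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_lollipop_csv <- function(change_table, path) {
  utils::write.csv(as.data.frame(change_table), path, row.names = FALSE)
  invisible(path)
}

#' Habitat-level summary with ANOVA and Tukey HSD
#'
#' Mean +/- sd of a metric per habitat, a one-way ANOVA across habitats,
#' and Tukey-adjusted pairwise comparisons (Tukey-Kramer for unequal n).
#' With a single habitat the tests are skipped with a note.
#'
#' @param habitat Habitat label per plot.
#' @param values Metric value per plot.
#' @return List: `summary` (habitat, n, mean, sd), `anova` (F, df, p) or
#'   NULL, `tukey` (pairwise table) or NULL, `note`.
#' @export
habitat_summary <- function(habitat, values) {
  habitat <- factor(habitat)
  summ <- data.frame(
    habitat = levels(habitat),
    n = as.integer(table(habitat)),
    mean = as.numeric(tapply(values, habitat, mean)),
    sd = as.numeric(tapply(values, habitat, stats::sd)))
  if (nlevels(habitat) < 2)
    return(list(summary = summ, anova = NULL, tukey = NULL,
                note = "single habitat: tests skipped"))
  fit <- stats::aov(values ~ habitat)
  at <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$habitat
  list(summary = summ,
       anova = list(F = at$`F value`[1], df = at$Df, p = at$`Pr(>F)`[1]),
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       note = NULL)
}
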
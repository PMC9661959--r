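# Shared fixtures and independent brute-force oracles.

tiny_spec <- function(n = 5, res = 30) grid_spec(n, n, res)

# A small landscape with both rivers crossing cropland and all five classes.
fixture_bundle <- function(seed = 11, n = 60) {
  generate_landscape(grid_spec(n, n), seed = seed)
}

# Brute-force pixel-centre distance to target pixels (oracle for the
# separable distance transform).
brute_distance <- function(mask, spec) {
  ctr <- pixel_centres(spec)
  tgt <- which(mask)
  rc <- arrayInd(tgt, dim(mask))
  txy <- pixel_centres(spec, rc[, 1], rc[, 2])
  d <- vapply(seq_len(nrow(ctr)), function(i)
    min(sqrt((ctr[i, 1] - txy[, 1])^2 + (ctr[i, 2] - txy[, 2])^2)),
    numeric(1))
  matrix(d, spec$n_rows, spec$n_cols)
}

# Brute-force circular focal statistic at one focal cell (oracle).
brute_focal <- function(values, spec, r0, c0, radius, stat = "mean") {
  f <- pixel_centres(spec, r0, c0)
  acc <- c()
  for (r in seq_len(spec$n_rows)) for (c in seq_len(spec$n_cols)) {
    p <- pixel_centres(spec, r, c)
    if (sqrt(sum((p - f)^2)) <= radius + 1e-9 && !is.na(values[r, c]))
      acc <- c(acc, values[r, c])
  }
  if (stat == "mean") mean(acc)
  else sqrt(mean(acc^2) - mean(acc)^2)
}

# Exhaustive-search oracle for one forward-selection step: the candidate
# (among `remaining`) minimising Wilks' Lambda of selected + candidate,
# computed independently through a MANOVA decomposition.
oracle_wilks <- function(X, y, cols) {
  M <- as.matrix(X[, cols, drop = FALSE])
  if (ncol(M) == 1) {
    a <- stats::anova(stats::lm(M[, 1] ~ factor(y)))
    return(a[2, "Sum Sq"] / sum(a[, "Sum Sq"]))
  }
  fit <- stats::manova(M ~ factor(y))
  summary(fit, test = "Wilks")$stats[1, "Wilks"]
}
oracle_step_pick <- function(X, y, selected, remaining) {
  lam <- vapply(remaining, function(cand)
    oracle_wilks(X, y, c(selected, cand)), numeric(1))
  remaining[which.min(lam)]
}
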
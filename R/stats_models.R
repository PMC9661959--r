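#' Gaussian GLM (simple linear regression) with deviance explained
#'
#' Least-squares fit of `y ~ x`; deviance explained is 1 - RSS/TSS, the
#' Gaussian-family analogue of R^2.
#'
#' @param x Predictor (non-constant).
#' @param y Response.
#' @return A `glm_fit`: coefficients (intercept, slope), deviance_explained,
#'   df_residual, residuals, fitted.
#' @export
fit_glm_gaussian <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need n >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("no variation in predictor", call. = FALSE)
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = c(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2])),
    deviance_explained = if (tss > 0) 1 - rss / tss else NA_real_,
    df_residual = length(y) - 2L, rss = rss,
    residuals = fit$residuals, fitted = fit$fitted.values,
    n = length(y), n_param = 2L), class = "glm_fit")
}

#' Regression-spline smooth fit
#'
#' Natural cubic regression spline of `y` on `x` (basis dimension `df`,
#' default 4), fit by least squares. The spline span contains all linear
#' functions, so the straight-line model is nested within it and the two can
#' be compared by an F test ([compare_models()]).
#'
#' @param x Predictor.
#' @param y Response.
#' @param df Spline basis dimension (> 1, < n).
#' @return A `smooth_fit` with rss, df_residual, fitted, residuals.
#' @export
fit_smooth <- function(x, y, df = 4) {
  if (df <= 1) stop("smooth df must exceed 1", call. = FALSE)
  if (df >= length(x)) stop("smooth df must be < n", call. = FALSE)
  B <- cbind(1, splines::ns(x, df = df))
  fit <- stats::lm.fit(B, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    deviance_explained = if (tss > 0) 1 - rss / tss else NA_real_,
    df_residual = length(y) - (df + 1L), rss = rss,
    residuals = fit$residuals, fitted = fit$fitted.values,
    n = length(y), n_param = df + 1L), class = "smooth_fit")
}

#' Choose between a straight-line and a smooth fit
#'
#' Nested-model F test on residual sums of squares; the simpler (GLM) model
#' is chosen when the test is not significant at `alpha`, following the
#' principle of preferring the simpler model unless the data demand the
#' smooth.
#'
#' @param glm_fit A [fit_glm_gaussian()] result.
#' @param smooth_fit A [fit_smooth()] result on the same data.
#' @param alpha Significance level (default 0.05).
#' @return List: chosen ("glm"/"smooth"), fit, F, p_value.
#' @export
compare_models <- function(glm_fit, smooth_fit, alpha = 0.05) {
  if (glm_fit$n != smooth_fit$n)
    stop("fits are not on the same data (different n)", call. = FALSE)
  df_diff <- smooth_fit$n_param - glm_fit$n_param
  rss_diff <- glm_fit$rss - smooth_fit$rss
  if (df_diff <= 0 || rss_diff <= 0 || smooth_fit$rss <= 0 ||
      smooth_fit$df_residual < 1) {
    Fv <- 0; pv <- 1
  } else {
    Fv <- (rss_diff / df_diff) / (smooth_fit$rss / smooth_fit$df_residual)
    pv <- stats::pf(Fv, df_diff, smooth_fit$df_residual, lower.tail = FALSE)
  }
  chosen <- if (pv < alpha) "smooth" else "glm"
  list(chosen = chosen,
       fit = if (chosen == "glm") glm_fit else smooth_fit,
       F = Fv, p_value = pv)
}

#' Moran's I spatial autocorrelation with normal-approximation test
#'
#' @param values Numeric vector (non-constant, n >= 4).
#' @param coords n x 2 coordinate matrix.
#' @param weights `"inverse_distance"` (1/d over all pairs) or `"rook"`
#'   (pairs at the minimum positive spacing, i.e. orthogonal grid
#'   neighbours).
#' @param row_standardize Row-standardise the weight matrix (default TRUE).
#' @return List: I, expected (-1/(n-1)), sd, z, p_value (two-sided, normal
#'   approximation under normality).
#' @export
morans_i <- function(values, coords,
                     weights = c("inverse_distance", "rook"),
                     row_standardize = TRUE) {
  weights <- match.arg(weights)
  n <- length(values)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: Moran's I undefined for constant values",
         call. = FALSE)
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  if (weights == "inverse_distance") {
    W[d > 0] <- 1 / d[d > 0]
  } else {
    dmin <- min(d[d > 0])
    W[abs(d - dmin) < 1e-6 * dmin] <- 1
  }
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
  }
  z <- values - mean(values)
  S0 <- sum(W)
  I <- (n / S0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  zs <- (I - EI) / sqrt(varI)
  list(I = I, expected = EI, sd = sqrt(varI), z = zs,
       p_value = 2 * stats::pnorm(-abs(zs)))
}

#' Proportional-odds (cumulative-logit) ordinal regression
#'
#' Maximum-likelihood fit of logit P(Y <= k) = theta_k - x'beta for ordinal
#' `y` coded 0..K-1, by BFGS with analytic gradients on a parameterisation
#' that keeps the thresholds strictly increasing. With K = 2 this reduces to
#' logistic regression (beta identical, theta_1 = -intercept).
#'
#' @param y Integer ordinal response 0..K-1 (>= 2 observed categories).
#' @param X Data frame or matrix of predictors.
#' @return An `ordinal_fit`: thresholds (increasing), coefficients,
#'   log_likelihood, AIC, n.
#' @export
fit_proportional_odds <- function(y, X) {
  X <- as.matrix(as.data.frame(X))
  y <- as.integer(y)
  lev <- sort(unique(y))
  if (length(lev) < 2)
    stop("non-convergence: fewer than 2 observed outcome categories",
         call. = FALSE)
  # compress to observed categories for fitting, keep labels
  yy <- match(y, lev) - 1L
  K <- length(lev)
  p <- ncol(X)
  n <- length(yy)
  f <- function(z) ifelse(is.finite(z), stats::dlogis(z), 0)

  thetas_from <- function(par) {
    a <- par[p + 1]
    if (K > 2) a <- cumsum(c(a, exp(par[(p + 2):(p + K - 1)])))
    a
  }
  nll <- function(par) {
    beta <- par[seq_len(p)]
    th <- c(-Inf, thetas_from(par), Inf)
    eta <- drop(X %*% beta)
    pr <- stats::plogis(th[yy + 2] - eta) - stats::plogis(th[yy + 1] - eta)
    -sum(log(pmax(pr, 1e-300)))
  }
  grad <- function(par) {
    beta <- par[seq_len(p)]
    th <- c(-Inf, thetas_from(par), Inf)
    eta <- drop(X %*% beta)
    u <- th[yy + 2] - eta; l <- th[yy + 1] - eta
    pr <- pmax(stats::plogis(u) - stats::plogis(l), 1e-300)
    fu <- f(u); fl <- f(l)
    gb <- colSums(X * ((fu - fl) / pr))
    gth <- numeric(K - 1)
    for (k in seq_len(K - 1))
      gth[k] <- -sum(ifelse(yy == k - 1, fu, 0) / pr) +
        sum(ifelse(yy == k, fl, 0) / pr)
    # chain rule to (a1, log-diffs)
    ga <- numeric(K - 1)
    ga[1] <- sum(gth)
    if (K > 2)
      for (j in 2:(K - 1))
        ga[j] <- sum(gth[j:(K - 1)]) * exp(par[p + j])
    c(gb, ga)
  }
  cum <- pmin(pmax(cumsum(tabulate(yy + 1, K))[-K] / n, 1e-3), 1 - 1e-3)
  th0 <- stats::qlogis(cum)
  th0 <- th0 + cumsum(c(0, rep(1e-3, K - 2)))  # enforce strict increase
  par0 <- c(rep(0, p), th0[1],
            if (K > 2) log(pmax(diff(th0), 1e-3)))
  opt <- stats::optim(par0, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  beta <- opt$par[seq_len(p)]
  if (opt$convergence != 0 || any(abs(beta) > 15))
    stop("non-convergence in proportional-odds fit (possible complete ",
         "separation); largest |coefficient| = ",
         sprintf("%.2f", max(abs(beta))), call. = FALSE)
  th <- thetas_from(opt$par)
  names(beta) <- colnames(X)
  names(th) <- paste(lev[-K], lev[-1], sep = "|")
  npar <- p + K - 1
  structure(list(thresholds = th, coefficients = beta,
                 log_likelihood = -opt$value,
                 AIC = 2 * npar + 2 * opt$value, n = n,
                 categories = lev), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> %d categories, n = %d, AIC = %.1f\n",
              length(x$categories), x$n, x$AIC))
  print(x$coefficients)
  invisible(x)
}

#' Linear model with a single random intercept
#'
#' Profiled maximum-likelihood (or REML) fit of
#' y = X beta + b\[group\] + e, b ~ N(0, sigma_b^2), e ~ N(0, sigma_e^2),
#' by 1-d optimisation over the variance ratio. ML is the default so AICs
#' are comparable across fixed-effect structures fitted to the same data.
#'
#' @param y Response vector.
#' @param X_fixed Data frame/matrix of fixed-effect covariates (intercept
#'   added automatically), or NULL for an intercept-only model.
#' @param group Grouping factor (villages); a single group yields an OLS
#'   fit with random variance 0 and a warning.
#' @param REML Use REML instead of ML (default FALSE).
#' @return A `mixed_fit`: coefficients table (estimate, se), sigma_b,
#'   sigma_e, logLik, AIC, method.
#' @export
fit_random_intercept_lm <- function(y, X_fixed = NULL, group,
                                    REML = FALSE) {
  group <- as.factor(group)
  n <- length(y)
  X <- if (is.null(X_fixed)) matrix(1, n, 1,
                                    dimnames = list(NULL, "(Intercept)"))
  else {
    M <- as.matrix(as.data.frame(X_fixed))
    cbind(`(Intercept)` = 1, M)
  }
  p <- ncol(X)
  single <- nlevels(group) < 2
  if (single)
    warning("single group: random-intercept variance not estimable, ",
            "reporting 0", call. = FALSE)
  idx <- split(seq_len(n), group)
  nj <- lengths(idx)

  profile <- function(lambda) {
    # accumulate X'V^-1 X etc. with V_j^-1 = I - c_j * J
    XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
    logdet <- 0
    for (j in seq_along(idx)) {
      ii <- idx[[j]]
      cj <- lambda / (1 + lambda * nj[j])
      sx <- colSums(X[ii, , drop = FALSE]); sy <- sum(y[ii])
      XtX <- XtX - cj * tcrossprod(sx)
      Xty <- Xty - cj * sx * sy
      yty <- yty - cj * sy^2
      logdet <- logdet + log(1 + lambda * nj[j])
    }
    beta <- solve(XtX, Xty)
    # r'V^-1 r via the normal equations: beta' X'V^-1 X beta = beta' X'V^-1 y
    rvr <- max(yty - sum(beta * Xty), 1e-12)
    if (REML) {
      s2 <- rvr / (n - p)
      dev <- (n - p) * log(2 * pi * s2) + logdet +
        determinant(XtX, logarithm = TRUE)$modulus + (n - p)
    } else {
      s2 <- rvr / n
      dev <- n * log(2 * pi * s2) + logdet + n
    }
    list(dev = as.numeric(dev), beta = beta, s2 = s2, XtX = XtX)
  }
  if (single) {
    lam_hat <- 0
  } else {
    obj <- function(t) profile(exp(t))$dev
    op <- stats::optimize(obj, c(-15, 15), tol = 1e-10)
    lam_hat <- if (profile(0)$dev <= op$objective) 0 else exp(op$minimum)
  }
  fit <- profile(lam_hat)
  vb <- fit$s2 * solve(fit$XtX)
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(fit$beta),
                      se = sqrt(diag(vb)))
  npar <- p + 2  # fixed effects + two variances
  logLik <- -fit$dev / 2
  structure(list(coefficients = coefs,
                 sigma_b = sqrt(lam_hat * fit$s2),
                 sigma_e = sqrt(fit$s2),
                 logLik = logLik, AIC = 2 * npar - 2 * logLik,
                 method = if (REML) "REML" else "ML",
                 n = n, n_groups = nlevels(group)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit> n = %d, %d groups (%s); sigma_b = %.3f, sigma_e = %.3f, AIC = %.1f\n",
    x$n, x$n_groups, x$method, x$sigma_b, x$sigma_e, x$AIC))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Rank-based AUC of scores against binary labels (Mann-Whitney).
auc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
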
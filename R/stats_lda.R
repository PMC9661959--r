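# Within-class (W) and total (T) corrected cross-product matrices.
.scatter <- function(X, y) {
  X <- as.matrix(X)
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  W <- matrix(0, ncol(X), ncol(X))
  for (g in unique(y)) {
    Xi <- X[y == g, , drop = FALSE]
    if (nrow(Xi) > 1)
      W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  list(W = W, T = Tm)
}

#' Wilks' Lambda for a covariate subset
#'
#' Lambda = det(W) / det(T) over the subset columns, where W is the pooled
#' within-class and T the total corrected cross-product matrix. Lambda = 1
#' iff class means coincide on the subset; 0 means perfect separation.
#'
#' @param X Samples x covariates matrix or data frame.
#' @param y Class labels (>= 2 classes, each >= 1 sample).
#' @param subset Column indices or names (default: all columns).
#' @return Lambda in \[0, 1\].
#' @export
wilks_lambda <- function(X, y, subset = NULL) {
  X <- as.matrix(as.data.frame(X))
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  if (length(unique(y)) < 2)
    stop("need >= 2 classes", call. = FALSE)
  s <- .scatter(X, y)
  dT <- det(s$T)
  if (!is.finite(dT) || abs(dT) < .Machine$double.eps * max(1, sum(diag(s$T))))
    stop("degenerate covariates: total scatter matrix is singular",
         call. = FALSE)
  max(det(s$W) / dT, 0)
}

#' Greedy forward covariate selection on Wilks' Lambda
#'
#' At each step the candidate minimising the Wilks' Lambda of
#' (selected + candidate) is added if its partial-F test rejects at
#' `p_enter`; selection stops otherwise. Candidates that make the total
#' scatter singular are skipped with a warning. Deterministic given inputs.
#'
#' @param X Samples x covariates (data frame or matrix with column names).
#' @param y Class labels.
#' @param p_enter Entry significance threshold (default 0.05).
#' @return List: `selected` (names in entry order) and `path` (data frame
#'   with per-step Lambda, partial F, p-value).
#' @export
greedy_wilks_forward <- function(X, y, p_enter = 0.05) {
  X <- as.data.frame(X)
  y <- as.factor(y)
  n <- nrow(X); g <- nlevels(y)
  selected <- character(0)
  lambda_old <- 1
  path <- data.frame(covariate = character(0), lambda = numeric(0),
                     F_partial = numeric(0), p_value = numeric(0))
  candidates <- names(X)
  repeat {
    p <- length(selected)
    df2 <- n - g - p
    if (df2 < 1 || length(candidates) == 0) break
    lam <- rep(NA_real_, length(candidates))
    for (i in seq_along(candidates)) {
      lam[i] <- tryCatch(
        wilks_lambda(X, y, c(selected, candidates[i])),
        error = function(e) {
          warning(sprintf("skipping candidate '%s': %s", candidates[i],
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
    }
    if (all(is.na(lam))) break
    best <- which.min(lam)
    lambda_new <- lam[best]
    Fp <- (df2 / (g - 1)) * (lambda_old / lambda_new - 1)
    pv <- stats::pf(Fp, g - 1, df2, lower.tail = FALSE)
    if (!is.finite(pv) || pv >= p_enter) break
    selected <- c(selected, candidates[best])
    path <- rbind(path, data.frame(covariate = candidates[best],
                                   lambda = lambda_new, F_partial = Fp,
                                   p_value = pv))
    candidates <- candidates[-best]
    lambda_old <- lambda_new
  }
  list(selected = selected, path = path)
}

#' Fit a linear discriminant model
#'
#' Gaussian equal-covariance classifier: per-class mean vectors, pooled
#' within-class covariance, and class priors (empirical frequencies by
#' default). A near-singular pooled covariance is ridge-inflated
#' (eps = 1e-8 x trace) with a warning.
#'
#' @param X Samples x covariates (columns are the model covariates).
#' @param y Class labels.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return An `lda_model`: covariate_names, class_labels, class_means,
#'   pooled_cov, priors, class_counts.
#' @export
fit_lda <- function(X, y, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  X <- as.matrix(as.data.frame(X))
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  n <- nrow(X); g <- nlevels(y)
  means <- matrix(NA_real_, g, ncol(X),
                  dimnames = list(levels(y), colnames(X)))
  for (l in levels(y)) means[l, ] <- colMeans(X[y == l, , drop = FALSE])
  s <- .scatter(X, y)
  S <- s$W / (n - g)
  eps <- 1e-8 * sum(diag(S))
  if (inherits(try(solve(S), silent = TRUE), "try-error") ||
      rcond(S) < 1e-12) {
    warning("pooled covariance near-singular; applying ridge inflation",
            call. = FALSE)
    S <- S + diag(max(eps, 1e-12), ncol(S))
  }
  pr <- if (priors == "uniform") rep(1 / g, g) else
    as.numeric(table(y)) / n
  structure(list(covariate_names = colnames(X), class_labels = levels(y),
                 class_means = means, pooled_cov = S, priors = pr,
                 class_counts = as.numeric(table(y))),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s) on %d covariates\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              length(x$covariate_names)))
  invisible(x)
}

# Posterior probabilities for a plain matrix of points.
.lda_posterior <- function(model, X) {
  X <- as.matrix(X)
  Sinv <- solve(model$pooled_cov)
  M <- model$class_means
  # linear discriminant scores: x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log pi_k
  A <- Sinv %*% t(M)                       # p x K
  const <- -0.5 * colSums(t(M) * A) + log(model$priors)
  scores <- X %*% A + matrix(const, nrow(X), ncol(A), byrow = TRUE)
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  post <- e / rowSums(e)
  colnames(post) <- model$class_labels
  post
}

#' Posterior class probabilities from a fitted LDA model
#'
#' @param model An `lda_model`.
#' @param newdata Either a data frame/matrix of points (must contain all
#'   model covariates) or a `covariate_stack`, in which case one posterior
#'   probability raster per class is returned.
#' @return Matrix of posteriors (points), or a named list of
#'   [raster_grid()]s summing to 1 per pixel (stack).
#' @export
predict_lda <- function(model, newdata) {
  if (inherits(newdata, "covariate_stack")) {
    missing <- setdiff(model$covariate_names, names(newdata$layers))
    if (length(missing))
      stop("schema error: stack lacks model covariate(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- vapply(model$covariate_names,
                function(nm) as.vector(newdata$layers[[nm]]$values),
                numeric(newdata$spec$n_rows * newdata$spec$n_cols))
    post <- .lda_posterior(model, X)
    out <- lapply(seq_along(model$class_labels), function(k)
      raster_grid(newdata$spec,
                  matrix(post[, k], newdata$spec$n_rows)))
    names(out) <- model$class_labels
    return(out)
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$covariate_names, names(newdata))
  if (length(missing))
    stop("schema error: newdata lacks model covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  .lda_posterior(model, as.matrix(newdata[, model$covariate_names,
                                          drop = FALSE]))
}

#' Serialize / restore an LDA model as JSON
#'
#' @param model An `lda_model`.
#' @param path File path.
#' @return `lda_to_json` invisibly returns `path`; `lda_from_json` the
#'   restored model.
#' @export
lda_to_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname lda_to_json
#' @export
lda_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr) {
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    matrix(as.numeric(m), nrow = nr,
           ncol = length(x$covariate_names))
  }
  x$class_means <- as_mat(x$class_means, length(x$class_labels))
  dimnames(x$class_means) <- list(x$class_labels, x$covariate_names)
  x$pooled_cov <- as_mat(x$pooled_cov, length(x$covariate_names))
  structure(x, class = "lda_model")
}
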
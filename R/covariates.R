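#' Landcover class labels
#'
#' Integer codes 1..5 for the five-class landcover mosaic used throughout:
#' forest, grassland, cropland, water, settlement.
#' @export
LANDCOVER_CLASSES <- c("forest", "grassland", "cropland", "water",
                       "settlement")

landcover_code <- function(class) {
  i <- match(class, LANDCOVER_CLASSES)
  if (any(is.na(i)))
    stop("unknown landcover class: ", paste(class[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

# Felzenszwalb & Huttenlocher 1-d squared distance transform (lower
# envelope of parabolas). f is squared distance in cell units; large finite
# stands in for +Inf so the envelope arithmetic stays defined.
.dt1d <- function(f) {
  n <- length(f)
  if (n == 1) return(f)
  v <- integer(n); z <- numeric(n + 1); d <- numeric(n)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

.LARGE <- 1e12  # sentinel "no target seen yet"; real sq distances < 1e10

#' Euclidean distance to the nearest target pixel
#'
#' Exact pixel-centre Euclidean distance (two-pass separable transform, not
#' a chamfer approximation). Zero on target pixels.
#'
#' @param landcover A categorical [raster_grid()] (or any raster when
#'   `target_mask` is given).
#' @param target A landcover class name, an integer code, or NULL when
#'   `target_mask` is supplied.
#' @param target_mask Optional logical matrix marking target pixels directly.
#' @return A [raster_grid()] of distances in metres.
#' @export
distance_to_class <- function(landcover, target = NULL, target_mask = NULL) {
  if (is.null(target_mask)) {
    code <- if (is.character(target)) landcover_code(target) else target
    target_mask <- !is.na(landcover$values) & landcover$values == code
  }
  if (!any(target_mask)) {
    lab <- if (is.character(target)) target else "mask"
    stop(sprintf("empty target: no '%s' pixels to measure distance to", lab),
         call. = FALSE)
  }
  f <- matrix(.LARGE, nrow(target_mask), ncol(target_mask))
  f[target_mask] <- 0
  for (j in seq_len(ncol(f))) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- .dt1d(f[i, ])
  raster_grid(landcover$spec, sqrt(f) * landcover$spec$resolution)
}

# Offsets (dr, dc) whose centre-to-centre distance is <= radius.
.window_offsets <- function(radius, resolution) {
  k <- floor(radius / resolution)
  dr <- rep(-k:k, times = 2 * k + 1)
  dc <- rep(-k:k, each = 2 * k + 1)
  keep <- (dr^2 + dc^2) * resolution^2 <= radius^2 + 1e-9
  cbind(dr = dr[keep], dc = dc[keep])
}

# Accumulate sum / count / sum-of-squares of in-window neighbours by
# shifting the value matrix over each offset (NA-aware).
.focal_accumulate <- function(values, offsets) {
  nr <- nrow(values); nc <- ncol(values)
  ok <- !is.na(values)
  v0 <- values; v0[!ok] <- 0
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1]; dc <- offsets[i, 2]
    # focal rows r receive neighbour rows r + dr
    fr <- max(1, 1 - dr):min(nr, nr - dr)
    fc <- max(1, 1 - dc):min(nc, nc - dc)
    sr <- fr + dr; sc <- fc + dc
    s[fr, fc]  <- s[fr, fc]  + v0[sr, sc, drop = FALSE]
    s2[fr, fc] <- s2[fr, fc] + v0[sr, sc, drop = FALSE]^2
    n[fr, fc]  <- n[fr, fc]  + ok[sr, sc, drop = FALSE]
  }
  list(sum = s, sumsq = s2, count = n)
}

#' Circular-window focal statistics
#'
#' Statistic over all pixels whose centres lie within `radius` metres of the
#' focal pixel centre (focal pixel included). Edge windows use the available
#' in-extent pixels only; `sd` is the population standard deviation.
#'
#' @param layer A [raster_grid()].
#' @param radius Window radius in metres (>= resolution).
#' @param stat `"mean"` or `"sd"`.
#' @return A [raster_grid()].
#' @export
focal_stats <- function(layer, radius, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  res <- layer$spec$resolution
  if (radius < res)
    stop("`radius` must be at least one pixel (>= resolution)", call. = FALSE)
  acc <- .focal_accumulate(layer$values, .window_offsets(radius, res))
  m <- acc$sum / acc$count
  out <- if (stat == "mean") m else sqrt(pmax(acc$sumsq / acc$count - m^2, 0))
  out[acc$count == 0] <- NA_real_
  raster_grid(layer$spec, out)
}

#' Percent cover of a class in a circular window
#'
#' 100 x (target pixels in window) / (valid pixels in window).
#'
#' @param landcover Categorical [raster_grid()].
#' @param target Class name or integer code.
#' @param radius Window radius in metres (default 250).
#' @return A [raster_grid()] in percent, range \[0, 100\].
#' @export
percent_class_in_window <- function(landcover, target, radius = 250) {
  code <- if (is.character(target)) landcover_code(target) else target
  ind <- matrix(NA_real_, landcover$spec$n_rows, landcover$spec$n_cols)
  ok <- !is.na(landcover$values)
  ind[ok] <- as.numeric(landcover$values[ok] == code)
  lay <- raster_grid(landcover$spec, ind)
  out <- focal_stats(lay, radius, "mean")
  out$values <- out$values * 100
  out
}

#' Greedy collinearity filter on sampled covariates
#'
#' Scans covariates in their declared (column) order and drops any whose
#' absolute Pearson correlation with an already-retained covariate reaches
#' the threshold, so the retained set is pairwise |r| < threshold.
#' Zero-variance covariates are dropped with a warning (their correlation is
#' undefined).
#'
#' @param samples Data frame or matrix, points x covariates.
#' @param threshold Absolute correlation at/above which the later covariate
#'   is dropped (default 0.7).
#' @return Character vector of retained covariate names, in order.
#' @export
correlation_filter <- function(samples, threshold = 0.7) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 3) stop("need >= 3 sample points", call. = FALSE)
  if (ncol(samples) < 1) stop("need >= 1 covariate", call. = FALSE)
  kept <- character(0)
  for (nm in names(samples)) {
    v <- samples[[nm]]
    if (stats::sd(v) == 0) {
      warning(sprintf("dropping zero-variance covariate '%s'", nm),
              call. = FALSE)
      next
    }
    r <- vapply(kept, function(k) abs(stats::cor(v, samples[[k]])), 0)
    if (all(r < threshold)) kept <- c(kept, nm)
  }
  kept
}

#' Assemble the landscape-configuration covariate stack
#'
#' Derives the full predictor stack from a landscape bundle: the five
#' distance layers (forest, river, road, settlement, industrial plantation),
#' canopy closure, NDVI, population density, canopy height, percent forest
#' in a 250 m window, and mean/sd of canopy closure and NDVI in 150 m and
#' 500 m windows (18 layers).
#'
#' @param bundle A [generate_landscape()] bundle (or any list with the same
#'   fields).
#' @return A `covariate_stack`: list with `spec`, named `layers` (each a
#'   [raster_grid()]), and `provenance = "baseline"`.
#' @export
build_stack <- function(bundle) {
  spec <- bundle$landcover$spec
  lc <- bundle$landcover
  dist_or_fail <- function(target, mask = NULL, name) {
    tryCatch(distance_to_class(lc, target, target_mask = mask),
             error = function(e)
               stop(sprintf("layer '%s': %s", name, conditionMessage(e)),
                    call. = FALSE))
  }
  river_mask <- rasterize_polylines_mask(spec, bundle$rivers)
  road_mask <- rasterize_polylines_mask(spec, bundle$roads)
  layers <- list(
    canopy_closure = bundle$canopy_closure,
    dist_forest = dist_or_fail("forest", name = "dist_forest"),
    dist_river = dist_or_fail(NULL, river_mask, "dist_river"),
    dist_road = dist_or_fail(NULL, road_mask, "dist_road"),
    dist_settlement = dist_or_fail("settlement", name = "dist_settlement"),
    dist_plantation = dist_or_fail(NULL, bundle$plantation_mask,
                                   "dist_plantation"),
    ndvi = bundle$ndvi,
    pct_forest_250 = percent_class_in_window(lc, "forest", 250),
    cc_mean_150 = focal_stats(bundle$canopy_closure, 150, "mean"),
    cc_sd_150 = focal_stats(bundle$canopy_closure, 150, "sd"),
    cc_mean_500 = focal_stats(bundle$canopy_closure, 500, "mean"),
    cc_sd_500 = focal_stats(bundle$canopy_closure, 500, "sd"),
    ndvi_mean_150 = focal_stats(bundle$ndvi, 150, "mean"),
    ndvi_sd_150 = focal_stats(bundle$ndvi, 150, "sd"),
    ndvi_mean_500 = focal_stats(bundle$ndvi, 500, "mean"),
    ndvi_sd_500 = focal_stats(bundle$ndvi, 500, "sd"),
    pop_density = bundle$pop_density,
    canopy_height = bundle$canopy_height)
  structure(list(spec = spec, layers = layers, provenance = "baseline"),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers (%s): %s\n", length(x$layers),
              x$provenance, paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract a covariate stack at point coordinates
#'
#' @param stack A `covariate_stack`.
#' @param x,y Point coordinates (metres), inside the extent.
#' @param point_id Optional point identifiers.
#' @return Data frame: point_id, x, y, one column per layer.
#' @export
extract_stack <- function(stack, x, y, point_id = seq_along(x)) {
  out <- data.frame(point_id = point_id, x = x, y = y)
  for (nm in names(stack$layers))
    out[[nm]] <- extract_at(stack$layers[[nm]], x, y)
  out
}
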
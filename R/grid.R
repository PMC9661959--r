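#' Grid specification for a planar raster
#'
#' All rasters in a session share one planar grid: origin at the top-left
#' corner, x increasing eastwards, y increasing northwards, square pixels.
#' The centre of cell (r, c) (1-based) is at
#' (origin_x + (c - 0.5) * resolution, origin_y - (r - 0.5) * resolution).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param resolution Pixel edge length in metres (default 30, the working
#'   resolution of the covariate maps).
#' @param origin_x,origin_y Map coordinates of the top-left corner (metres).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, resolution = 30,
                      origin_x = 0, origin_y = n_rows * resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1)
    stop("`n_rows` and `n_cols` must be >= 1", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, resolution = resolution,
         origin_x = origin_x, origin_y = origin_y),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d @ %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$resolution, x$origin_x, x$origin_y))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$resolution - b$resolution) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Pixel-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Optional 1-based row/column indices (vectorised,
#'   recycled pairwise). Defaults to all cells in column-major order.
#' @return A two-column matrix (x, y) of centre coordinates in metres.
#' @export
pixel_centres <- function(spec, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(spec$n_rows), times = spec$n_cols)
    cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  }
  cbind(x = spec$origin_x + (cols - 0.5) * spec$resolution,
        y = spec$origin_y - (rows - 0.5) * spec$resolution)
}

#' Map coordinates to raster cell indices
#'
#' @param spec A [grid_spec()].
#' @param x,y Coordinates in metres.
#' @return A two-column integer matrix (row, col); coordinates outside the
#'   extent raise a bounds error.
#' @export
cell_from_xy <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$resolution) + 1L
  row <- floor((spec$origin_y - y) / spec$resolution) + 1L
  bad <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the raster extent", sum(bad)),
         call. = FALSE)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster layer on a grid
#'
#' A thin matrix container: `values` is an n_rows x n_cols numeric (or
#' integer-coded categorical) matrix; NA encodes nodata and is excluded from
#' all derived statistics.
#'
#' @param spec A [grid_spec()].
#' @param values Matrix of values (or a single value to fill), dims matching
#'   `spec`.
#' @param categories Optional character vector naming integer codes
#'   1..length(categories) for categorical layers.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(spec, values, categories = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1)
    values <- matrix(values, spec$n_rows, spec$n_cols)
  if (!is.matrix(values) || nrow(values) != spec$n_rows ||
      ncol(values) != spec$n_cols)
    stop("`values` dimensions do not match the grid spec", call. = FALSE)
  structure(list(spec = spec, values = values, categories = categories),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<raster_grid> %d x %d @ %g m; range [%g, %g]; %d nodata\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$resolution,
              rng[1], rng[2], sum(is.na(x$values))))
  if (!is.null(x$categories))
    cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Extract raster values at point coordinates
#'
#' @param raster A [raster_grid()].
#' @param x,y Point coordinates in metres (must fall inside the extent).
#' @return Numeric vector of cell values at the points.
#' @export
extract_at <- function(raster, x, y) {
  rc <- cell_from_xy(raster$spec, x, y)
  raster$values[cbind(rc[, "row"], rc[, "col"])]
}

stopifnot_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a$spec, b$spec))
    stop(sprintf("grid mismatch: %s do not share one grid spec", what),
         call. = FALSE)
}

#' Evaluate code with a temporarily seeded RNG
#'
#' Seeds the RNG, evaluates `code`, and restores (or clears) the global
#' RNG state afterwards, so the package's generators stay pure functions of
#' (arguments, seed) without touching global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Rotate a matrix 90 degrees clockwise (used by rotation-invariance tests
# and documented as part of the covariate-engine contract).
rotate90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
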
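# Polylines are lists of n x 2 matrices (columns x, y, metres), e.g. one
# matrix per river. Villages are an n x 2 matrix of points.

as_polylines <- function(x) {
  if (is.matrix(x)) x <- list(x)
  lapply(x, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("polyline must have 2 columns (x, y)",
                           call. = FALSE)
    colnames(m) <- c("x", "y")
    m
  })
}

# Minimum distance from points (px, py) to one segment (x1,y1)-(x2,y2).
.dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from every pixel centre to a polyline set
#'
#' Exact point-to-segment Euclidean distance, evaluated at pixel centres.
#'
#' @param spec A [grid_spec()].
#' @param polylines List of n x 2 coordinate matrices.
#' @return A [raster_grid()] of distances in metres.
#' @export
distance_to_polylines <- function(spec, polylines) {
  polylines <- as_polylines(polylines)
  if (length(polylines) == 0)
    stop("empty polyline set", call. = FALSE)
  ctr <- pixel_centres(spec)
  d <- rep(Inf, nrow(ctr))
  for (line in polylines) {
    if (nrow(line) == 1) {
      d <- pmin(d, sqrt((ctr[, 1] - line[1, 1])^2 +
                          (ctr[, 2] - line[1, 2])^2))
      next
    }
    for (i in seq_len(nrow(line) - 1)) {
      d <- pmin(d, .dist_to_segment(ctr[, 1], ctr[, 2],
                                    line[i, 1], line[i, 2],
                                    line[i + 1, 1], line[i + 1, 2]))
    }
  }
  raster_grid(spec, matrix(d, spec$n_rows, spec$n_cols))
}

# Logical mask of cells traversed by any polyline (1-pixel rasterization:
# points sampled every quarter-resolution along each segment).
rasterize_polylines_mask <- function(spec, polylines) {
  mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  if (is.null(polylines) || length(polylines) == 0) return(mask)
  polylines <- as_polylines(polylines)
  step <- spec$resolution / 4
  for (line in polylines) {
    pts <- line
    if (nrow(line) > 1) {
      acc <- list()
      for (i in seq_len(nrow(line) - 1)) {
        p1 <- line[i, ]; p2 <- line[i + 1, ]
        len <- sqrt(sum((p2 - p1)^2))
        t <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
        acc[[i]] <- cbind(p1[1] + t * (p2[1] - p1[1]),
                          p1[2] + t * (p2[2] - p1[2]))
      }
      pts <- do.call(rbind, acc)
    }
    inside <- pts[, 1] >= spec$origin_x &
      pts[, 1] <= spec$origin_x + spec$n_cols * spec$resolution &
      pts[, 2] <= spec$origin_y &
      pts[, 2] >= spec$origin_y - spec$n_rows * spec$resolution
    pts <- pts[inside, , drop = FALSE]
    if (nrow(pts) == 0) next
    # clamp boundary coordinates into the closest cell
    eps <- 1e-9
    px <- pmin(pmax(pts[, 1], spec$origin_x + eps),
               spec$origin_x + spec$n_cols * spec$resolution - eps)
    py <- pmin(pmax(pts[, 2], spec$origin_y - spec$n_rows * spec$resolution +
                      eps), spec$origin_y - eps)
    rc <- cell_from_xy(spec, px, py)
    mask[unique(rc[, c("row", "col"), drop = FALSE])] <- TRUE
  }
  mask
}
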
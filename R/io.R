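# Raster I/O uses the ESRI ASCII grid format (.asc): a plain-text header
# (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
# of values top to bottom, readable by GDAL/terra/QGIS. Chosen over GeoTIFF
# so the package has no binary-format dependency.

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for NA cells (default -9999).
#' @return The path, invisibly.
#' @export
write_raster <- function(raster, path, nodata = -9999) {
  spec <- raster$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$resolution),
    sprintf("cellsize %.10g", spec$resolution),
    sprintf("NODATA_value %g", nodata)), con)
  v <- raster$values
  v[is.na(v)] <- nodata
  for (r in seq_len(spec$n_rows))
    writeLines(paste(format(v[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File path.
#' @param expect_spec Optional [grid_spec()]; a resolution/extent mismatch
#'   with the session grid raises a grid-mismatch error.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, expect_spec = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  spec <- grid_spec(nr, nc, resolution = hdr$cellsize,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize)
  if (!is.null(expect_spec) && !same_grid(spec, expect_spec))
    stop("grid mismatch: raster on file does not match the session grid",
         call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(spec, m)
}

#' Write polylines or points as GeoJSON
#'
#' @param features For `"LineString"`: a list of n x 2 coordinate matrices;
#'   for `"Point"`: an n x 2 matrix.
#' @param path Output path.
#' @param type `"LineString"` or `"Point"`.
#' @param names Optional feature names.
#' @return The path, invisibly.
#' @export
write_geojson <- function(features, path, type = c("LineString", "Point"),
                          names = NULL) {
  type <- match.arg(type)
  if (type == "Point") features <- lapply(seq_len(nrow(features)),
                                          function(i) features[i, , drop = FALSE])
  feats <- lapply(seq_along(features), function(i) {
    coords <- unname(as.matrix(features[[i]]))
    geom <- if (type == "Point")
      list(type = "Point", coordinates = as.numeric(coords[1, ]))
    else
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(coords)),
                                function(r) as.numeric(coords[r, ])))
    list(type = "Feature",
         properties = list(name = if (is.null(names)) paste0("f", i)
                           else names[i]),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON polylines or points written by [write_geojson()]
#'
#' @param path File path.
#' @return List of coordinate matrices (LineStrings) or an n x 2 matrix
#'   (Points).
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- g$features
  types <- vapply(feats, function(f) f$geometry$type, "")
  if (all(types == "Point")) {
    m <- t(vapply(feats, function(f)
      as.numeric(unlist(f$geometry$coordinates)), numeric(2)))
    colnames(m) <- c("x", "y")
    return(m)
  }
  lapply(feats, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  })
}

#' Write a landscape bundle to a directory
#'
#' One ASCII grid per raster layer, GeoJSON for rivers/roads/villages, and
#' the generator config as JSON.
#'
#' @param bundle A landscape bundle.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rl <- list(landcover = bundle$landcover,
             canopy_closure = bundle$canopy_closure,
             ndvi = bundle$ndvi, pop_density = bundle$pop_density,
             canopy_height = bundle$canopy_height,
             plantation_mask = raster_grid(bundle$landcover$spec,
                                           bundle$plantation_mask * 1))
  for (nm in names(rl)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_raster(rl[[nm]], p)
    paths <- c(paths, p)
  }
  if (length(bundle$rivers) > 0) {
    p <- file.path(dir, "rivers.geojson")
    write_geojson(bundle$rivers, p, "LineString")
    paths <- c(paths, p)
  }
  if (length(bundle$roads) > 0) {
    p <- file.path(dir, "roads.geojson")
    write_geojson(bundle$roads, p, "LineString")
    paths <- c(paths, p)
  }
  if (!is.null(bundle$villages)) {
    p <- file.path(dir, "villages.geojson")
    write_geojson(bundle$villages, p, "Point",
                  names = rownames(bundle$villages))
    paths <- c(paths, p)
  }
  p <- file.path(dir, "landscape_config.json")
  jsonlite::write_json(bundle$config, p, auto_unbox = TRUE, digits = NA)
  c(paths, p)
}
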
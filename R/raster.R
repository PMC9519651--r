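#' Lightweight planar raster
#'
#' A single-band raster on a regular grid in a projected metric CRS. Values
#' are stored as a matrix `z[ix, iy]` with x increasing along rows and y
#' increasing along columns; cell centres are at
#' `xmin + (ix - 0.5) * cell`, `ymin + (iy - 0.5) * cell`.
#'
#' @param z numeric matrix of cell values (`nx` by `ny`).
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell cell size in meters; must be positive.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(z, xmin, ymin, cell) {
  if (!is.matrix(z)) stop("'z' must be a matrix")
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0) {
    stop("cell size must be a single positive number")
  }
  structure(
    list(z = z, xmin = xmin, ymin = ymin, cell = cell,
         nx = nrow(z), ny = ncol(z)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cell, x$xmin, x$ymin))
  cat(sprintf("  values: [%g, %g], %d missing\n",
              suppressWarnings(min(x$z, na.rm = TRUE)),
              suppressWarnings(max(x$z, na.rm = TRUE)), sum(is.na(x$z))))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#' @param r a `grid_raster`.
#' @return list with numeric vectors `x` (length nx) and `y` (length ny).
#' @export
raster_axes <- function(r) {
  list(x = r$xmin + (seq_len(r$nx) - 0.5) * r$cell,
       y = r$ymin + (seq_len(r$ny) - 0.5) * r$cell)
}

#' All cell centres of a raster as a two-column matrix
#' @param r a `grid_raster`.
#' @return matrix with columns x, y; rows ordered x-fastest (column-major in z).
#' @export
raster_cells <- function(r) {
  ax <- raster_axes(r)
  cbind(x = rep(ax$x, times = r$ny), y = rep(ax$y, each = r$nx))
}

#' Extract raster values at point locations (nearest-cell rule)
#'
#' Each point receives the value of the cell containing it. Points outside
#' the raster extent yield `NA`; the number of such points is reported via a
#' warning so dropped covariates are visible in pipeline logs.
#'
#' @param points two-column matrix or data.frame with x and y in meters.
#' @param raster a `grid_raster`.
#' @return numeric vector of cell values, `NA` outside the extent.
#' @export
extract_raster <- function(points, raster) {
  if (!inherits(raster, "grid_raster")) stop("'raster' must be a grid_raster")
  if (length(raster$z) == 0L) stop("empty raster")
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  ix <- floor((pts[, 1] - raster$xmin) / raster$cell) + 1L
  iy <- floor((pts[, 2] - raster$ymin) / raster$cell) + 1L
  # a point exactly on the max edge belongs to the last cell
  ix[pts[, 1] == raster$xmin + raster$nx * raster$cell] <- raster$nx
  iy[pts[, 2] == raster$ymin + raster$ny * raster$cell] <- raster$ny
  ok <- ix >= 1L & ix <= raster$nx & iy >= 1L & iy <= raster$ny & !is.na(ix) & !is.na(iy)
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- raster$z[cbind(ix[ok], iy[ok])]
  if (any(!ok)) {
    warning(sprintf("%d point(s) outside raster extent set to NA", sum(!ok)))
  }
  out
}

#' NDVI from red and near-infrared reflectance rasters
#'
#' Computes the Normalized Difference Vegetation Index
#' `(NIR - red) / (NIR + red)` cellwise. Cells where both bands are zero
#' (0/0) are set to missing.
#'
#' @param red,nir co-registered `grid_raster`s of nonnegative reflectance.
#' @return a `grid_raster` of NDVI values in \[-1, 1\].
#' @export
ndvi_from_bands <- function(red, nir) {
  .check_same_grid(list(red, nir))
  if (any(red$z < 0, na.rm = TRUE) || any(nir$z < 0, na.rm = TRUE)) {
    stop("reflectance values must be nonnegative")
  }
  den <- nir$z + red$z
  z <- (nir$z - red$z) / den
  z[den == 0] <- NA_real_
  grid_raster(z, red$xmin, red$ymin, red$cell)
}

#' Cellwise mean of co-registered rasters
#'
#' Missing cells are ignored per cell: a cell missing in one layer takes the
#' mean of the remaining layers (multi-year NDVI composites are built this
#' way).
#'
#' @param rasters non-empty list of co-registered `grid_raster`s.
#' @return a `grid_raster` of cellwise means.
#' @export
average_rasters <- function(rasters) {
  if (length(rasters) == 0L) stop("empty raster list")
  .check_same_grid(rasters)
  zs <- lapply(rasters, `[[`, "z")
  n_ok <- Reduce(`+`, lapply(zs, function(z) !is.na(z)))
  tot <- Reduce(`+`, lapply(zs, function(z) {
    z[is.na(z)] <- 0
    z
  }))
  z <- tot / n_ok
  z[n_ok == 0] <- NA_real_
  r1 <- rasters[[1L]]
  grid_raster(z, r1$xmin, r1$ymin, r1$cell)
}

.check_same_grid <- function(rasters) {
  r1 <- rasters[[1L]]
  for (r in rasters[-1L]) {
    if (!inherits(r, "grid_raster") || !inherits(r1, "grid_raster")) {
      stop("all inputs must be grid_raster objects")
    }
    if (r$nx != r1$nx || r$ny != r1$ny || r$cell != r1$cell ||
        r$xmin != r1$xmin || r$ymin != r1$ymin) {
      stop("rasters are not co-registered (shape/origin/cell mismatch)")
    }
  }
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (readable by QGIS/GDAL). Rows are
#' written north to south as the format requires.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata value used for missing cells.
#' @export
write_raster_asc <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$nx),
    sprintf("nrows %d", r$ny),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$cell),
    sprintf("NODATA_value %g", nodata)
  ), con)
  z <- r$z
  z[is.na(z)] <- nodata
  for (iy in rev(seq_len(r$ny))) {
    writeLines(paste(formatC(z[, iy], format = "g", digits = 8), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#' @param path file path.
#' @return a `grid_raster` with NODATA cells as `NA`.
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  m <- matrix(vals, nrow = nx, ncol = ny)  # read rows north->south, x fastest
  z <- m[, rev(seq_len(ny)), drop = FALSE]
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA_real_
  grid_raster(z, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}
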
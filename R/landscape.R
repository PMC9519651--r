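#' Generate synthetic tree-cover and NDVI rasters
#'
#' Stationary random fields with controllable spatial autocorrelation:
#' white noise smoothed with a Gaussian kernel (separable 1-D convolution
#' along each axis, kernel SD = `smoothness` meters), then min-max rescaled
#' into the legal range of each variable -- tree cover into \[0, 100\] %,
#' NDVI into `ndvi_range` (default \[-0.2, 0.9\], the span seen over water /
#' bare ground to dense spring vegetation). Identical seeds give identical
#' rasters.
#'
#' @param extent_m either `c(width, height)` with origin (0, 0), or
#'   `c(xmin, xmax, ymin, ymax)`, in meters; must divide into whole cells.
#' @param cell_m cell size in meters (> 0).
#' @param seed integer seed.
#' @param smoothness Gaussian kernel SD in meters (> 0); larger values give
#'   stronger cell-to-cell autocorrelation.
#' @param ndvi_range length-2 numeric range for the NDVI field.
#' @return list with `grid_raster`s `cover` and `ndvi` on the same grid.
#' @export
generate_landscape <- function(extent_m, cell_m, seed = 1L, smoothness = 200,
                               ndvi_range = c(-0.2, 0.9)) {
  if (!is.numeric(cell_m) || cell_m <= 0) stop("non-positive cell size")
  if (!is.numeric(smoothness) || smoothness <= 0) stop("smoothness must be > 0")
  ext <- as.numeric(extent_m)
  if (length(ext) == 1L) ext <- c(ext, ext)
  if (length(ext) == 2L) ext <- c(0, ext[1L], 0, ext[2L])
  w <- ext[2L] - ext[1L]; h <- ext[4L] - ext[3L]
  if (w < cell_m || h < cell_m) stop("extent smaller than one cell")
  nx <- w / cell_m; ny <- h / cell_m
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("extent must divide into whole cells")
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  with_seed(seed, {
    cover_z <- .smooth_field(nx, ny, cell_m, smoothness)
    ndvi_z <- .smooth_field(nx, ny, cell_m, smoothness)
    list(
      cover = grid_raster(.rescale(cover_z, 0, 100), ext[1L], ext[3L], cell_m),
      ndvi = grid_raster(.rescale(ndvi_z, ndvi_range[1L], ndvi_range[2L]),
                         ext[1L], ext[3L], cell_m)
    )
  })
}

# white noise smoothed by separable Gaussian convolution (kernel SD in meters)
.smooth_field <- function(nx, ny, cell, sd_m) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  kx <- .gauss_band(nx, cell, sd_m)
  ky <- .gauss_band(ny, cell, sd_m)
  kx %*% z %*% t(ky)
}

.gauss_band <- function(n, cell, sd_m) {
  pos <- (seq_len(n) - 1) * cell
  k <- outer(pos, pos, function(a, b) stats::dnorm(a - b, sd = sd_m))
  k / rowSums(k)
}

.rescale <- function(z, lo, hi) {
  r <- range(z)
  if (r[1L] == r[2L]) return(matrix((lo + hi) / 2, nrow(z), ncol(z)))
  lo + (z - r[1L]) / (r[2L] - r[1L]) * (hi - lo)
}

#' Lag-1 spatial autocorrelation of a raster
#'
#' Moran-type statistic: the correlation between each cell and its immediate
#' neighbour, averaged over the x and y directions. Used to verify that the
#' `smoothness` parameter controls field roughness.
#'
#' @param r a `grid_raster`.
#' @return correlation in \[-1, 1\].
#' @export
lag1_autocorrelation <- function(r) {
  z <- r$z
  cx <- stats::cor(as.vector(z[-nrow(z), ]), as.vector(z[-1L, ]))
  cy <- stats::cor(as.vector(z[, -ncol(z)]), as.vector(z[, -1L]))
  mean(c(cx, cy))
}
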
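#' Fixed-kernel utilization distribution of relocations
#'
#' Bivariate Gaussian kernel density on a regular grid, padded at least
#' three bandwidths beyond the data extent so that effectively all mass lies
#' on the grid; the surface is renormalised to integrate to exactly 1.
#' The "reference" bandwidth is the Silverman/Worton-type plug-in
#' `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`.
#'
#' Computation uses `MASS::kde2d`, whose bandwidth argument equals four
#' kernel SDs; the conversion is handled here so `bandwidth` is always the
#' kernel SD in meters.
#'
#' @param points data.frame or matrix with `x`, `y` in meters (>= 5 points).
#' @param bandwidth kernel SD in meters, or `"reference"`.
#' @param cell_m grid cell size in meters (default 20, the covariate raster
#'   resolution).
#' @param pad_bw padding beyond the data extent, in bandwidths.
#' @return object of class `density_surface`: fields `z` (nx x ny), `x`,
#'   `y` (cell-centre axes), `cell`, `bandwidth`.
#' @export
kde_surface <- function(points, bandwidth = "reference", cell_m = 20, pad_bw = 3) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(pts) < 5L) stop("need >= 5 points")
  sdx <- stats::sd(pts[, 1]); sdy <- stats::sd(pts[, 2])
  if (sdx == 0 && sdy == 0) stop("all points identical: zero variance")
  if (identical(bandwidth, "reference")) {
    bandwidth <- sqrt((sdx^2 + sdy^2) / 2) * nrow(pts)^(-1 / 6)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0 or 'reference'")
  pad <- pad_bw * bandwidth
  x0 <- min(pts[, 1]) - pad; x1 <- max(pts[, 1]) + pad
  y0 <- min(pts[, 2]) - pad; y1 <- max(pts[, 2]) + pad
  nx <- max(16L, ceiling((x1 - x0) / cell_m) + 1L)
  ny <- max(16L, ceiling((y1 - y0) / cell_m) + 1L)
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bandwidth, n = c(nx, ny),
                   lims = c(x0, x0 + (nx - 1L) * cell_m,
                            y0, y0 + (ny - 1L) * cell_m))
  mass <- sum(k$z) * cell_m^2
  structure(list(z = k$z / mass, x = k$x, y = k$y, cell = cell_m,
                 bandwidth = bandwidth, n_points = nrow(pts)),
            class = "density_surface")
}

#' Total probability mass of a density surface
#' @param surface a `density_surface`.
#' @return numeric scalar (1 up to numerical tolerance).
#' @export
surface_mass <- function(surface) sum(surface$z) * surface$cell^2

#' Isopleth (home-range) region of a utilization distribution
#'
#' Finds the smallest density threshold whose super-level cell set contains
#' at least `level` of the total mass: cells are sorted by density
#' (descending) and accumulated, with ties at the threshold all included.
#' The cell set is polygonised into boundary contour rings.
#'
#' @param surface a `density_surface`.
#' @param level probability level in (0, 1); 0.99 delimits availability.
#' @return object of class `isopleth`: `level`, `threshold`, `mask`
#'   (logical matrix over the surface grid), `area` (m2), `contained_mass`,
#'   boundary `polygons` (list of two-column matrices), and the grid axes.
#' @export
isopleth_polygon <- function(surface, level = 0.99) {
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  z <- surface$z
  if (all(z == 0) || any(!is.finite(z))) stop("degenerate density surface")
  cell_mass <- as.vector(z) * surface$cell^2
  ord <- order(cell_mass, decreasing = TRUE)
  cum <- cumsum(cell_mass[ord])
  k <- which(cum >= level * sum(cell_mass))[1L]
  threshold <- as.vector(z)[ord[k]]
  mask <- z >= threshold
  contained <- sum(cell_mass[as.vector(mask)]) / sum(cell_mass)
  cl <- grDevices::contourLines(surface$x, surface$y, z, levels = threshold)
  polygons <- lapply(cl, function(c1) cbind(c1$x, c1$y))
  # order rings by enclosed area so polygons[[1]] is the main range
  if (length(polygons) > 1L) {
    polygons <- polygons[order(vapply(polygons, polygon_area, numeric(1)),
                               decreasing = TRUE)]
  }
  structure(list(level = level, threshold = threshold, mask = mask,
                 x = surface$x, y = surface$y, cell = surface$cell,
                 area = sum(mask) * surface$cell^2,
                 contained_mass = contained,
                 polygons = polygons),
            class = "isopleth")
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("<isopleth> level %.2f: area %.3f km2, contained mass %.4f, %d ring(s)\n",
              x$level, x$area / 1e6, x$contained_mass, length(x$polygons)))
  invisible(x)
}

#' Test whether points fall inside an isopleth region
#' @param iso an `isopleth`.
#' @param points two-column matrix/data.frame of coordinates.
#' @return logical vector.
#' @export
point_in_isopleth <- function(iso, points) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  ix <- round((pts[, 1] - iso$x[1L]) / iso$cell) + 1L
  iy <- round((pts[, 2] - iso$y[1L]) / iso$cell) + 1L
  ok <- ix >= 1L & ix <= length(iso$x) & iy >= 1L & iy <= length(iso$y)
  out <- rep(FALSE, nrow(pts))
  out[ok] <- iso$mask[cbind(ix[ok], iy[ok])]
  out
}

#' Sample available locations from a home range, paired to used fixes
#'
#' Draws exactly `ratio` uniform random locations inside the isopleth region
#' for every used location. Each available point inherits the timestamp --
#' and therefore every temporal label present in the used table (treatment,
#' time of day, season, calving, rut) -- of its paired used point, and gets
#' response 0. Sampling picks an isopleth cell uniformly and jitters within
#' it, which is exactly uniform over the (cell-set) region.
#'
#' @param iso an `isopleth`.
#' @param used data.frame of used points (must contain `x`, `y`; a
#'   `response` column is set to 1 on output for the used rows convention).
#' @param ratio available points per used point (>= 1).
#' @param seed integer seed.
#' @return data.frame of available points with `response = 0`.
#' @export
sample_available <- function(iso, used, ratio = 16, seed = 1L) {
  if (ratio < 1) stop("ratio must be >= 1")
  cells <- which(iso$mask, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("empty isopleth")
  n <- ratio * nrow(used)
  keep <- setdiff(names(used), c("x", "y", "response"))
  av <- used[rep(seq_len(nrow(used)), each = ratio), keep, drop = FALSE]
  with_seed(seed, {
    pick <- sample.int(nrow(cells), n, replace = TRUE)
    half <- iso$cell / 2
    av$x <- iso$x[cells[pick, 1L]] + stats::runif(n, -half, half)
    av$y <- iso$y[cells[pick, 2L]] + stats::runif(n, -half, half)
  })
  av$response <- 0
  rownames(av) <- NULL
  av
}

#' Use:available ratio sensitivity analysis
#'
#' Refits the RSF model with fresh availability draws at each candidate
#' ratio and reports how much the coefficients move between consecutive
#' ratios. The change of coefficient j between consecutive ratios is
#' measured relative to its magnitude, floored at one standard error:
#' `|b_j(r) - b_j(r')| / max(|b_j(r')|, se_j(r'))`. The selected ratio is
#' the smallest one from which every subsequent consecutive change stays
#' below `tol` (default 5%).
#'
#' @param used data.frame of used points with raw covariates attached
#'   (see [attach_covariates()]); `response` is set to 1 internally.
#' @param iso an `isopleth` to sample availability from.
#' @param terms model terms (see [build_design()]).
#' @param ratios ascending integer vector of candidate ratios (>= 2 values).
#' @param seed integer seed.
#' @param tol relative stability tolerance.
#' @param nAGQ quadrature nodes for the refits.
#' @param cover,ndvi,sites rasters and sites used to attach covariates to
#'   the sampled available points.
#' @return data.frame (ratio, one column per coefficient, `max_delta`);
#'   the chosen ratio in `attr(, "selected_ratio")`.
#' @export
ratio_sensitivity <- function(used, iso, terms, ratios, cover, ndvi, sites,
                              seed = 1L, tol = 0.05, nAGQ = 1) {
  ratios <- as.integer(ratios)
  if (length(ratios) < 2L) stop("need >= 2 ratios")
  if (is.unsorted(ratios, strictly = TRUE)) stop("ratios must be sorted ascending")
  used$response <- 1
  fits <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    av <- sample_available(iso, used, ratio = ratios[i], seed = seed + i)
    av <- attach_covariates(av, cover, ndvi, sites)
    dat <- prepare_model_data(rbind(used[names(av)], av))
    fits[[i]] <- tryCatch(
      fit_model(dat, terms, nAGQ = nAGQ),
      error = function(e) stop(sprintf("fit failed at ratio %d: %s",
                                       ratios[i], conditionMessage(e)))
    )
  }
  coefs <- lapply(fits, function(f) stats::setNames(f$coefficients$estimate,
                                                    f$coefficients$term))
  ses <- lapply(fits, function(f) stats::setNames(f$coefficients$se,
                                                  f$coefficients$term))
  shared <- Reduce(intersect, lapply(coefs, names))
  delta <- rep(NA_real_, length(ratios))
  for (i in seq_len(length(ratios) - 1L)) {
    later <- coefs[[i + 1L]][shared]
    floor_se <- pmax(abs(later), ses[[i + 1L]][shared])
    delta[i] <- max(abs(later - coefs[[i]][shared]) / floor_se)
  }
  stable_from <- NA_integer_
  for (i in seq_len(length(ratios) - 1L)) {
    if (all(delta[i:(length(ratios) - 1L)] < tol)) {
      stable_from <- ratios[i]
      break
    }
  }
  out <- cbind(data.frame(ratio = ratios),
               do.call(rbind, lapply(coefs, function(cf) as.data.frame(t(cf[shared])))),
               data.frame(max_delta = delta))
  attr(out, "selected_ratio") <- stable_from
  out
}
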
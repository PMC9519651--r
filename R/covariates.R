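#' Centre and scale a continuous covariate
#'
#' All continuous variables are scaled (z-standardised) before model
#' fitting; the parameters are stored so that predictions on new data and
#' map scoring use exactly the scaling of the fitted model.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @param center,scale optional fixed parameters; computed from `values`
#'   when `NULL`.
#' @return list with `scaled`, `mean`, `sd`.
#' @export
scale_continuous <- function(values, center = NULL, scale = NULL) {
  v <- as.numeric(values)
  if (is.null(center) || is.null(scale)) {
    if (length(unique(v[is.finite(v)])) < 2L) stop("need >= 2 distinct values to scale")
    center <- mean(v, na.rm = TRUE)
    scale <- stats::sd(v, na.rm = TRUE)
  }
  if (!is.finite(scale) || scale == 0) stop("zero variance: cannot scale")
  list(scaled = (v - center) / scale, mean = center, sd = scale)
}

#' Invert `scale_continuous`
#' @param scaled scaled values.
#' @param params list with `mean` and `sd` (as returned by [scale_continuous()]).
#' @return original-scale values.
#' @export
unscale_continuous <- function(scaled, params) {
  scaled * params$sd + params$mean
}

#' Attach environmental covariates to used/available points
#'
#' Adds raw tree cover, NDVI, distance-to-site (m) and the inside-site
#' indicator to a point table via nearest-cell raster extraction and exact
#' polygon distances.
#'
#' @param points data.frame with `x`, `y` columns.
#' @param cover,ndvi co-registered `grid_raster`s.
#' @param sites a `site_set`.
#' @return `points` with columns `cover_raw`, `ndvi_raw`, `dist_raw`,
#'   `inside` appended.
#' @export
attach_covariates <- function(points, cover, ndvi, sites) {
  .check_same_grid(list(cover, ndvi))
  xy <- as.matrix(points[, c("x", "y")])
  points$cover_raw <- extract_raster(xy, cover)
  points$ndvi_raw <- extract_raster(xy, ndvi)
  points$dist_raw <- distance_to_sites(xy, sites)
  points$inside <- point_in_sites(xy, sites)
  points
}

#' Prepare a modelling table: scaled covariates and quadratic terms
#'
#' Scales `cover_raw`, `ndvi_raw`, `dist_raw` into model columns `cover`,
#' `ndvi`, `dist` and adds their quadratics (`cover2`, `ndvi2`, `dist2`).
#' Quadratics are squares of the scaled variable. Scaling parameters are
#' either computed from the supplied (pooled used + available) data -- the
#' default, done once per seasonal dataset -- or passed in (e.g. a true
#' model's reference scaling, or a fitted model's stored scaling for map
#' prediction).
#'
#' @param points data.frame with `cover_raw`, `ndvi_raw`, `dist_raw`.
#' @param scaling optional named list of `list(mean=, sd=)` per variable
#'   (`cover`, `ndvi`, `dist`).
#' @return the augmented data.frame; scaling parameters in
#'   `attr(, "scaling")`.
#' @export
prepare_model_data <- function(points, scaling = NULL) {
  out <- points
  used_scaling <- list()
  for (v in c("cover", "ndvi", "dist")) {
    raw <- points[[paste0(v, "_raw")]]
    if (is.null(raw)) next
    sc <- if (!is.null(scaling[[v]])) {
      scale_continuous(raw, center = scaling[[v]]$mean, scale = scaling[[v]]$sd)
    } else {
      scale_continuous(raw)
    }
    out[[v]] <- sc$scaled
    out[[paste0(v, "2")]] <- sc$scaled^2
    used_scaling[[v]] <- list(mean = sc$mean, sd = sc$sd)
  }
  if (!is.null(out$treatment)) {
    out$treatment <- factor(as.character(out$treatment), levels = .treatment_levels)
  }
  if (!is.null(out$tod)) {
    out$tod <- factor(as.character(out$tod), levels = .tod_levels)
  }
  attr(out, "scaling") <- used_scaling
  out
}
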
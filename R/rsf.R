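#' Build an exponential resource selection function from a fitted model
#'
#' Retains exactly the coefficients of the fitted mixed logistic model with
#' Wald p < `alpha` (the intercept is always excluded) and carries the
#' covariate scaling parameters forward; the resulting RSF evaluates
#' `w(x) = exp(sum beta * x)` over the retained terms. Individual factor
#' levels (columns) are retained or dropped on their own p-values;
#' marginality of interactions is deliberately not enforced.
#'
#' @param fit a `fit_result` from [fit_model()].
#' @param alpha significance cut for retention (default 0.05; `alpha = 1`
#'   retains every non-intercept coefficient).
#' @return object of class `rsf_model` with `coefficients` (named numeric),
#'   `terms`, `xlevels`, `scaling`.
#' @export
build_rsf <- function(fit, alpha = 0.05) {
  cf <- fit$coefficients
  keep <- cf$term != "(Intercept)" & cf$p < alpha
  if (!any(keep)) stop("no significant coefficients to retain")
  structure(list(
    coefficients = stats::setNames(cf$estimate[keep], cf$term[keep]),
    terms = fit$terms,
    xlevels = fit$xlevels,
    scaling = fit$scaling,
    alpha = alpha
  ), class = "rsf_model")
}

#' @export
print.rsf_model <- function(x, ...) {
  cat(sprintf("<rsf_model> %d retained coefficient(s) (alpha = %g)\n",
              length(x$coefficients), x$alpha))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' RSF score w(x) for points under a scenario
#'
#' Evaluates `exp(sum beta * x)` over the retained coefficients, with the
#' same dummy/interaction expansion as the design matrix of the source fit.
#' Raw covariates (`cover_raw`, `ndvi_raw`, `dist_raw` -- %, index, meters)
#' are standardised with the model's stored scaling parameters; quadratics
#' are squares of the scaled values.
#'
#' @param model an `rsf_model`.
#' @param points data.frame with raw covariate columns needed by the model.
#' @param scenario named list of factor levels / flags (`treatment`, `tod`,
#'   `calving`, `rut`) applied to all points; per-point columns already in
#'   `points` are used where the scenario does not override them.
#' @return numeric vector of strictly positive scores (`NA` where a
#'   covariate is missing).
#' @export
rsf_score <- function(model, points, scenario = list()) {
  df <- as.data.frame(points)
  n <- nrow(df)
  cellvals <- data.frame(row.names = seq_len(n))
  for (v in c("cover", "ndvi", "dist")) {
    raw <- df[[paste0(v, "_raw")]] %||% df[[v]]
    if (!is.null(raw)) {
      if (is.null(model$scaling[[v]])) stop("model lacks scaling for ", v)
      cellvals[[v]] <- (raw - model$scaling[[v]]$mean) / model$scaling[[v]]$sd
      cellvals[[paste0(v, "2")]] <- cellvals[[v]]^2
    }
  }
  ctx <- function(var, default) {
    vals <- scenario[[var]] %||% df[[var]] %||% default
    rep_len(as.character(vals), n)
  }
  treatment <- ctx("treatment", "before")
  tod <- ctx("tod", "day")
  calving <- as.logical(ctx("calving", FALSE))
  rut <- as.logical(ctx("rut", FALSE))
  lp <- rep(0, n)
  for (nm in names(model$coefficients)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    val <- rep(1, n)
    for (p in parts) {
      val <- val * if (p %in% names(cellvals)) {
        cellvals[[p]]
      } else if (grepl("^treatment", p)) {
        as.numeric(paste0("treatment", treatment) == p)
      } else if (grepl("^tod", p)) {
        as.numeric(paste0("tod", tod) == p)
      } else if (p %in% c("calving", "calvingTRUE")) {
        as.numeric(calving)
      } else if (p %in% c("rut", "rutTRUE")) {
        as.numeric(rut)
      } else {
        stop("missing covariate for term part: ", p)
      }
    }
    lp <- lp + model$coefficients[[nm]] * val
  }
  exp(lp)
}

#' Predicted RSF-score map for one scenario
#'
#' Scores every landscape cell under a fixed scenario (one treatment /
#' time-of-day / flag setting per map). Distance to the grazing sites is
#' measured from cell centres (0 inside sites); cells with a missing
#' covariate get a missing score.
#'
#' @param model an `rsf_model`.
#' @param cover,ndvi co-registered `grid_raster`s of raw covariates.
#' @param sites a `site_set`.
#' @param scenario named list as in [rsf_score()].
#' @return a `grid_raster` of RSF scores.
#' @export
predict_map <- function(model, cover, ndvi, sites, scenario = list()) {
  .check_same_grid(list(cover, ndvi))
  cells <- raster_cells(cover)
  pts <- data.frame(
    cover_raw = as.vector(cover$z),
    ndvi_raw = as.vector(ndvi$z),
    dist_raw = distance_to_sites(cells, sites)
  )
  sc <- rsf_score(model, pts, scenario)
  grid_raster(matrix(sc, cover$nx, cover$ny), cover$xmin, cover$ymin, cover$cell)
}

#' Scale scores by their scenario-specific median
#'
#' For plotting score-distance profiles, scores are divided by the median
#' score of their scenario so profiles of different scenarios share a
#' reference level; ratios within a scenario are preserved.
#'
#' @param scores numeric vector of RSF scores.
#' @param scenario_id vector identifying each score's scenario.
#' @return numeric vector of relative scores.
#' @export
relative_scores <- function(scores, scenario_id) {
  if (all(is.na(scores))) stop("all scores missing")
  med <- stats::ave(scores, scenario_id,
                    FUN = function(v) stats::median(v, na.rm = TRUE))
  scores / med
}

#' Score-distance profile for displacement scenarios
#'
#' Evaluates the RSF along a gradient of raw distance-to-site (other
#' covariates held at fixed raw values) for each scenario, and scales each
#' profile by its scenario median. This is the profile used to read off how
#' far the selection peak sits from the grazing sites under each treatment.
#'
#' @param model an `rsf_model`.
#' @param distances numeric vector of raw distances (m).
#' @param scenarios named list of scenario lists (see [rsf_score()]).
#' @param cover_raw,ndvi_raw fixed raw covariate values for the profile.
#' @return data.frame (scenario, distance, score, rel_score).
#' @export
score_distance_profile <- function(model, distances, scenarios,
                                   cover_raw = 0, ndvi_raw = 0) {
  rows <- lapply(names(scenarios), function(id) {
    pts <- data.frame(cover_raw = cover_raw, ndvi_raw = ndvi_raw,
                      dist_raw = distances)
    data.frame(scenario = id, distance = distances,
               score = rsf_score(model, pts, scenarios[[id]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rel_score <- relative_scores(out$score, out$scenario)
  out
}
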
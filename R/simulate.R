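#' True selection model for synthetic telemetry
#'
#' The generating model of the synthetic-data module: a coefficient map over
#' the same design vocabulary as the fitted models (e.g. `dist`, `dist2`,
#' `dist:treatmentearly`, `cover`, `todnight`), an animal-level
#' random-intercept SD, and the reference scaling under which the
#' coefficients are defined. Coefficients act on covariates standardised
#' with that reference scaling, so estimates from a pipeline run using the
#' same scaling are directly comparable to the truth.
#'
#' @param coefficients named numeric vector of true coefficients.
#' @param re_sd SD of the zero-mean normal animal random intercept.
#' @param scaling named list per continuous variable with `mean` and `sd`
#'   (meters / % / index units).
#' @return object of class `true_model`.
#' @export
true_model <- function(coefficients, re_sd = 0.5, scaling = NULL) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be named")
  }
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  for (nm in setdiff(names(coefficients), "(Intercept)")) .check_term_name(nm)
  structure(list(coefficients = coefficients, re_sd = re_sd,
                 scaling = scaling), class = "true_model")
}

# vocabulary check for coefficient names: parts of a ':' product
.check_term_name <- function(nm) {
  parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
  ok <- vapply(parts, function(p) {
    p %in% c("cover", "cover2", "ndvi", "ndvi2", "dist", "dist2",
             "calving", "rut", "calvingTRUE", "rutTRUE") ||
      grepl("^treatment(before|early|ongoing|after)$", p) ||
      grepl("^tod(day|night|twilight)$", p)
  }, logical(1))
  if (!all(ok)) stop("unknown design term: ", nm)
  invisible(TRUE)
}

#' Bundle landscape, sites, schedule and reference settings into a study
#'
#' Precomputes the distance-to-site surface on the landscape grid so
#' simulation and map prediction share one covariate source.
#'
#' @param cover,ndvi co-registered `grid_raster`s.
#' @param sites a `site_set`.
#' @param schedule a `grazing_schedule`.
#' @param hunts optional Date vector of driven-hunt days.
#' @param lat,lon reference coordinate (deg) for solar computations.
#' @param utc_offset hours added to UTC for local calendar dates.
#' @return object of class `study`.
#' @export
make_study <- function(cover, ndvi, sites, schedule, hunts = NULL,
                       lat = 51.88, lon = 12.98, utc_offset = 1) {
  .check_same_grid(list(cover, ndvi))
  dist_z <- matrix(distance_to_sites(raster_cells(cover), sites),
                   cover$nx, cover$ny)
  structure(list(
    cover = cover, ndvi = ndvi,
    dist = grid_raster(dist_z, cover$xmin, cover$ymin, cover$cell),
    sites = sites, schedule = schedule, hunts = hunts,
    lat = lat, lon = lon, utc_offset = utc_offset
  ), class = "study")
}

# evaluate one coefficient term for cell covariate values under a context.
# cellvals: data.frame with scaled cover/ndvi/dist (+ quadratics); context:
# list(treatment=, tod=, calving=, rut=)
.term_value <- function(nm, cellvals, context) {
  parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
  val <- rep(1, nrow(cellvals))
  for (p in parts) {
    val <- val * if (p %in% names(cellvals)) {
      cellvals[[p]]
    } else if (grepl("^treatment", p)) {
      as.numeric(paste0("treatment", context$treatment) == p)
    } else if (grepl("^tod", p)) {
      as.numeric(paste0("tod", context$tod) == p)
    } else if (p %in% c("calving", "calvingTRUE")) {
      as.numeric(isTRUE(context$calving))
    } else if (p %in% c("rut", "rutTRUE")) {
      as.numeric(isTRUE(context$rut))
    } else {
      stop("cannot evaluate term part: ", p)
    }
  }
  val
}

# linear predictor over cells for a fixed temporal context
.lp_cells <- function(coefficients, cellvals, context) {
  lp <- rep(0, nrow(cellvals))
  for (nm in names(coefficients)) {
    if (nm == "(Intercept)") {
      lp <- lp + coefficients[[nm]]
    } else {
      lp <- lp + coefficients[[nm]] * .term_value(nm, cellvals, context)
    }
  }
  lp
}

# scaled covariate table for a set of landscape cells
.cell_covariates <- function(study, cells, scaling) {
  cov_raw <- extract_raster(cells, study$cover)
  ndvi_raw <- extract_raster(cells, study$ndvi)
  dist_raw <- extract_raster(cells, study$dist)
  sc <- function(v, raw) (raw - scaling[[v]]$mean) / scaling[[v]]$sd
  out <- data.frame(
    cover = sc("cover", cov_raw), ndvi = sc("ndvi", ndvi_raw),
    dist = sc("dist", dist_raw)
  )
  out$cover2 <- out$cover^2; out$ndvi2 <- out$ndvi^2; out$dist2 <- out$dist^2
  out
}

#' Simulate GPS telemetry for one animal from a true selection model
#'
#' Fixes are spaced exactly two hours apart. Each location is drawn
#' independently from the landscape cells inside the animal's home polygon
#' with probability proportional to `exp(linear predictor)` of the true
#' model, evaluated under that fix's temporal context (treatment window of
#' the animal's site group, time of day, calving/rut flags), then jittered
#' uniformly within the chosen cell. An animal-level intercept is drawn once
#' from `N(0, re_sd^2)`; because each fix is a normalised draw over cells it
#' does not alter placement, but it is part of the stated generative model.
#'
#' @param truth a `true_model` (must carry `scaling`).
#' @param study a `study`.
#' @param home_polygon two-column vertex matrix delimiting availability.
#' @param n_fixes number of fixes (>= 1).
#' @param start first timestamp (POSIXct UTC).
#' @param sex "female" or "male".
#' @param animal_id identifier string.
#' @param seed integer seed.
#' @return data.frame of relocations: `animal_id`, `timestamp`, `x`, `y`,
#'   `sex`, `quality_ok`.
#' @export
simulate_deer <- function(truth, study, home_polygon, n_fixes, start,
                          sex = "female", animal_id = "A1", seed = 1L) {
  stopifnot(inherits(truth, "true_model"), inherits(study, "study"), n_fixes >= 1)
  if (is.null(truth$scaling)) stop("true_model needs reference scaling")
  cells <- raster_cells(study$cover)
  inside <- .in_polygon(cells, as.matrix(home_polygon))
  if (!any(inside)) stop("home polygon contains no landscape cells")
  cells <- cells[inside, , drop = FALSE]
  cellvals <- .cell_covariates(study, cells, truth$scaling)
  group <- suppressWarnings(assign_site_group(home_polygon, study$sites))
  timestamps <- as.POSIXct(start, tz = "UTC") + 7200 * (seq_len(n_fixes) - 1)
  # animals whose group has no grazing terms are simply never treated
  treatment <- if (!is.na(group) &&
                   group %in% study$schedule$intervals$group) {
    assign_treatment(timestamps, study$schedule, group, study$utc_offset)
  } else {
    factor(rep("unassigned", n_fixes), levels = .treatment_levels)
  }
  tod <- classify_time_of_day(timestamps, study$lat, study$lon)
  flags <- flag_biological_periods(timestamps, sex, study$utc_offset)
  ctx_key <- paste(treatment, tod, flags$calving, flags$rut)
  with_seed(seed, {
    b0 <- stats::rnorm(1L, 0, truth$re_sd)
    x <- numeric(n_fixes); y <- numeric(n_fixes)
    half <- study$cover$cell / 2
    for (key in unique(ctx_key)) {
      idx <- which(ctx_key == key)
      i1 <- idx[1L]
      context <- list(treatment = as.character(treatment[i1]),
                      tod = as.character(tod[i1]),
                      calving = flags$calving[i1], rut = flags$rut[i1])
      w <- exp(b0 + .lp_cells(truth$coefficients, cellvals, context))
      if (!any(w > 0) || !all(is.finite(w))) stop("degenerate selection weights")
      pick <- sample.int(nrow(cells), length(idx), replace = TRUE, prob = w)
      x[idx] <- cells[pick, 1L] + stats::runif(length(idx), -half, half)
      y[idx] <- cells[pick, 2L] + stats::runif(length(idx), -half, half)
    }
    data.frame(animal_id = animal_id, timestamp = timestamps, x = x, y = y,
               sex = sex, quality_ok = TRUE, stringsAsFactors = FALSE)
  })
}

#' Simulate a binary site-use series
#'
#' Independent Bernoulli draws with probability `plogis(linear predictor)`
#' under each timestamp's temporal context (treatment, time of day,
#' calving/rut). The coefficient map must contain an `(Intercept)` and may
#' contain time-of-day and treatment terms and their interactions.
#'
#' @param use_params named numeric coefficient map (design vocabulary).
#' @param schedule a `grazing_schedule`.
#' @param timestamps POSIXct vector; every timestamp must fall inside a
#'   labelled treatment window of `group` (else an error).
#' @param seed integer seed.
#' @param group site group whose grazing terms apply.
#' @param sex "female" or "male" (drives the calving flag).
#' @param lat,lon,utc_offset solar/calendar reference.
#' @return integer 0/1 vector, one draw per timestamp.
#' @export
simulate_use_series <- function(use_params, schedule, timestamps, seed = 1L,
                                group = "north", sex = "female",
                                lat = 51.88, lon = 12.98, utc_offset = 1) {
  if (!"(Intercept)" %in% names(use_params)) stop("use_params needs an intercept")
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  treatment <- assign_treatment(timestamps, schedule, group, utc_offset)
  if (any(treatment == "unassigned")) {
    stop(sprintf("%d timestamp(s) outside schedule treatment coverage",
                 sum(treatment == "unassigned")))
  }
  tod <- classify_time_of_day(timestamps, lat, lon)
  flags <- flag_biological_periods(timestamps, sex, utc_offset)
  dummy <- data.frame(row.names = seq_along(timestamps))
  lp <- rep(0, length(timestamps))
  for (nm in names(use_params)) {
    if (nm == "(Intercept)") {
      lp <- lp + use_params[[nm]]
      next
    }
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    val <- rep(1, length(timestamps))
    for (p in parts) {
      val <- val * if (grepl("^treatment", p)) {
        as.numeric(paste0("treatment", as.character(treatment)) == p)
      } else if (grepl("^tod", p)) {
        as.numeric(paste0("tod", as.character(tod)) == p)
      } else if (p %in% c("calving", "calvingTRUE")) {
        as.numeric(flags$calving)
      } else if (p %in% c("rut", "rutTRUE")) {
        as.numeric(flags$rut)
      } else {
        stop("cannot evaluate term part in use_params: ", p)
      }
    }
    lp <- lp + use_params[[nm]] * val
  }
  with_seed(seed, stats::rbinom(length(lp), 1L, inv_logit(lp)))
}
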
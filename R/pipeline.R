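#' Attach temporal labels to relocations
#'
#' Adds time of day, season, calving/rut flags and the 21-day treatment
#' category (relative to the grazing terms of each animal's site group) to
#' a relocation table, and applies the quality screen and driven-hunt
#' exclusion.
#'
#' @param relocations data.frame of relocations (`animal_id`, `timestamp`,
#'   `x`, `y`, `sex`, `quality_ok`).
#' @param study a `study`.
#' @param group_of_animal named character vector mapping each animal id to
#'   its site group.
#' @return labelled data.frame; excluded-row counts in
#'   `attr(, "counts")`.
#' @export
label_relocations <- function(relocations, study, group_of_animal) {
  n0 <- nrow(relocations)
  keep <- if (is.null(relocations$quality_ok)) rep(TRUE, n0) else as.logical(relocations$quality_ok)
  df <- relocations[keep, , drop = FALSE]
  n_quality <- n0 - nrow(df)
  df <- exclude_hunt_windows(df, study$hunts %||% as.Date(character(0)),
                             study$utc_offset)
  n_hunt <- attr(df, "n_excluded")
  df$tod <- classify_time_of_day(df$timestamp, study$lat, study$lon)
  df$season <- assign_season(df$timestamp, study$utc_offset)
  flags <- flag_biological_periods(df$timestamp, df$sex, study$utc_offset)
  df$calving <- flags$calving
  df$rut <- flags$rut
  df$treatment <- factor(NA_character_, levels = .treatment_levels)
  for (a in unique(df$animal_id)) {
    g <- group_of_animal[[a]]
    if (is.null(g) || is.na(g)) next
    idx <- df$animal_id == a
    df$treatment[idx] <- assign_treatment(df$timestamp[idx], study$schedule,
                                          g, study$utc_offset)
  }
  attr(df, "counts") <- c(total = n0, quality_dropped = n_quality,
                          hunt_excluded = n_hunt)
  df
}

#' Per-animal 0.99 kernel home ranges
#'
#' Home ranges are built from all of an animal's fixes, independent of any
#' treatment filtering.
#'
#' @param relocations relocation table.
#' @param level isopleth level.
#' @param bandwidth,cell_m passed to [kde_surface()].
#' @return named list of `isopleth` objects, one per animal.
#' @export
home_ranges <- function(relocations, level = 0.99, bandwidth = "reference",
                        cell_m = 20) {
  animals <- unique(relocations$animal_id)
  out <- lapply(stats::setNames(animals, animals), function(a) {
    pts <- relocations[relocations$animal_id == a, c("x", "y")]
    isopleth_polygon(kde_surface(pts, bandwidth = bandwidth, cell_m = cell_m),
                     level = level)
  })
  out
}

#' Build the use-availability RSF dataset
#'
#' For each animal's used fixes, samples `ratio` availability points from
#' its home-range isopleth (paired timestamps carry all temporal labels),
#' attaches raw covariates to both, and returns the pooled table with
#' `response` 1/0.
#'
#' @param used labelled used fixes (rows already filtered to the analysis
#'   windows).
#' @param isopleths named list of per-animal `isopleth`s.
#' @param study a `study`.
#' @param ratio availability ratio (default 16).
#' @param seed integer seed.
#' @return data.frame of used + available points with raw covariates.
#' @export
build_rsf_dataset <- function(used, isopleths, study, ratio = 16, seed = 1L) {
  used$response <- 1
  parts <- list()
  animals <- unique(used$animal_id)
  for (i in seq_along(animals)) {
    a <- animals[i]
    u <- used[used$animal_id == a, , drop = FALSE]
    av <- sample_available(isopleths[[a]], u, ratio = ratio, seed = seed + i)
    parts[[i]] <- rbind(u, av[names(u)])
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- attach_covariates(out, study$cover, study$ndvi, study$sites)
  bad <- !stats::complete.cases(out[, c("cover_raw", "ndvi_raw", "dist_raw")])
  if (any(bad)) {
    message(sprintf("dropping %d point(s) with missing covariates (outside rasters)",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Demo configuration for the pipeline driver
#'
#' Small synthetic study (three grazing sites in two groups, a December
#' term plus a summer term, a handful of animals) sized so a full pipeline
#' run completes in well under a minute.
#'
#' @param out_dir output directory for the run.
#' @param seed integer seed.
#' @return config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("grazeRSF_run_"), seed = 42L) {
  list(
    out_dir = out_dir,
    seed = seed,
    lat = 51.88, lon = 12.98, utc_offset = 1,
    landscape = list(extent = 6000, cell = 50, smoothness = 300),
    years = c(2016L, 2017L),
    animals = list(n = 3L, n_fixes = 3000L, start = "2016-11-10 00:00:00",
                   home_radius = 1500),
    true_model = list(
      coefficients = c(dist = -0.6, dist2 = -0.35,
                       `dist:treatmentearly` = 0.35,
                       `dist:treatmentongoing` = 0.6,
                       `dist:treatmentafter` = 0.45),
      re_sd = 0.5,
      scaling = list(dist = list(mean = 1500, sd = 900),
                     cover = list(mean = 50, sd = 25),
                     ndvi = list(mean = 0.35, sd = 0.22))
    ),
    ratio = 4L,
    terms_use = c("tod", "treatment", "rut"),
    terms_rsf = c("cover", "cover2", "ndvi", "ndvi2", "dist", "dist2",
                  "treatment", "dist:treatment"),
    nAGQ = 1L,
    cv = list(k = 2L, n_bins = 10L)
  )
}

# default synthetic site layout mirroring the study's 62/22/102-ha pattern:
# one northern site, two southern sites, inside a square landscape
.default_sites <- function(extent) {
  w <- if (length(extent) == 2L) extent[1L] else extent
  cx <- w / 2
  rect <- function(x0, y0, wx, wy) {
    cbind(c(x0, x0 + wx, x0 + wx, x0), c(y0, y0, y0 + wy, y0 + wy))
  }
  site_set(
    polygons = list(
      rect(cx - 394, 0.72 * w, 788, 788),          # ~62 ha, north
      rect(cx - 1100, 0.18 * w, 470, 470),         # ~22 ha, south
      rect(cx + 200, 0.14 * w, 1010, 1010)         # ~102 ha, south
    ),
    site_id = c("N1", "S1", "S2"),
    group = c("north", "south", "south")
  )
}

# circular (32-gon) home polygon
.circle_polygon <- function(center, radius, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> label -> home ranges -> availability -> covariates
#' -> seasonal use models -> seasonal RSFs -> cross-validation, writing
#' coefficient tables, CV reports and a JSON manifest (inputs, seeds,
#' record counts, decisions) into `config$out_dir`. Any stage failure halts
#' with the stage name and cause. Identical config + seed gives identical
#' outputs.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file
#'   with the same structure.
#' @return the run directory path, invisibly; the collected results as
#'   attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("out_dir", "seed", "landscape", "animals", "true_model")) {
    if (is.null(config[[key]])) stop(sprintf("config missing key '%s'", key))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  counts <- list()

  sim <- stage("simulate", {
    ls <- config$landscape
    land <- generate_landscape(ls$extent, ls$cell, seed = config$seed,
                               smoothness = ls$smoothness)
    sites <- .default_sites(ls$extent)
    schedule <- generate_schedule(sites, config$years, seed = config$seed + 1L)
    hunts <- generate_hunts(config$years, seed = config$seed + 2L)
    study <- make_study(land$cover, land$ndvi, sites, schedule, hunts,
                        lat = config$lat %||% 51.88, lon = config$lon %||% 12.98,
                        utc_offset = config$utc_offset %||% 1)
    tm <- config$true_model
    truth <- true_model(unlist(tm$coefficients), re_sd = tm$re_sd,
                        scaling = tm$scaling)
    an <- config$animals
    groups <- unique(sites$group)
    relocs <- list()
    homes <- list()
    centers <- list(north = c(ls$extent / 2, 0.78 * ls$extent),
                    south = c(ls$extent / 2, 0.25 * ls$extent))
    for (i in seq_len(an$n)) {
      g <- groups[(i - 1L) %% length(groups) + 1L]
      ctr <- centers[[g]] + ((i * 37L) %% 11L - 5L) * 40
      home <- .circle_polygon(ctr, an$home_radius)
      id <- sprintf("deer%02d", i)
      homes[[id]] <- home
      relocs[[id]] <- simulate_deer(truth, study, home, an$n_fixes,
                                    start = as.POSIXct(an$start, tz = "UTC"),
                                    sex = if (i %% 3L == 0L) "male" else "female",
                                    animal_id = id, seed = config$seed + 10L + i)
    }
    list(study = study, truth = truth, relocs = do.call(rbind, relocs),
         homes = homes)
  })
  counts$fixes_simulated <- nrow(sim$relocs)

  hr <- stage("home_range", {
    home_ranges(sim$relocs, level = 0.99,
                cell_m = config$landscape$cell)
  })

  labelled <- stage("label", {
    grp <- vapply(names(hr), function(a) assign_site_group(hr[[a]], sim$study$sites),
                  character(1))
    label_relocations(sim$relocs, sim$study, grp)
  })
  counts$hunt_excluded <- unname(attr(labelled, "counts")["hunt_excluded"])

  used <- stage("filter", {
    keep <- labelled$treatment %in% c("before", "early", "ongoing", "after") &
      labelled$season != "excluded"
    droplevels(labelled[keep, , drop = FALSE])
  })
  counts$used_in_windows <- nrow(used)
  counts$per_treatment <- as.list(table(factor(as.character(used$treatment),
                                               levels = c("before", "early", "ongoing", "after"))))

  rsf_data <- stage("availability", {
    build_rsf_dataset(used, hr, sim$study, ratio = config$ratio %||% 16L,
                      seed = config$seed + 100L)
  })

  results <- list()
  for (season in c("winter", "summer")) {
    sdat <- rsf_data[rsf_data$season == season, , drop = FALSE]
    sused <- used[used$season == season, , drop = FALSE]
    if (nrow(sused) < 50L || length(unique(sused$animal_id)) < 2L) {
      results[[season]] <- list(skipped = "insufficient seasonal data")
      next
    }
    results[[season]] <- stage(paste0("fit_", season), {
      # use model: response is presence inside a grazing site
      sused$response <- point_in_sites(sused[, c("x", "y")], sim$study$sites)
      use_fit <- if (length(unique(sused$response)) > 1L) {
        fit_model(prepare_model_data(sused), config$terms_use,
                  nAGQ = config$nAGQ %||% 9L)
      } else {
        NULL
      }
      rsf_prep <- prepare_model_data(droplevels(sdat))
      rsf_fit <- fit_model(rsf_prep, config$terms_rsf, nAGQ = config$nAGQ %||% 9L)
      rsf <- tryCatch(build_rsf(rsf_fit), error = function(e) NULL)
      cv <- kfold_cv(rsf_prep, config$terms_rsf, k = config$cv$k %||% 5L,
                     blocking = "random", n_bins = config$cv$n_bins %||% 10L,
                     seed = config$seed + 200L, alpha = 1,
                     nAGQ = config$nAGQ %||% 1L)
      if (!is.null(use_fit)) {
        write_fit(use_fit, file.path(config$out_dir, sprintf("use_model_%s.csv", season)),
                  file.path(config$out_dir, sprintf("use_model_%s.json", season)))
      }
      write_fit(rsf_fit, file.path(config$out_dir, sprintf("rsf_%s.csv", season)),
                file.path(config$out_dir, sprintf("rsf_%s.json", season)))
      utils::write.csv(cv$folds, file.path(config$out_dir, sprintf("cv_%s.csv", season)),
                       row.names = FALSE)
      list(use_fit = use_fit, rsf_fit = rsf_fit, rsf = rsf, cv = cv,
           recovery = recovery_report(sim$truth, rsf_fit))
    })
  }

  stage("manifest", {
    jsonlite::write_json(list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC", usetz = FALSE),
      seed = config$seed,
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("grazeRSF")),
      counts = counts,
      seasons = lapply(results, function(r) {
        if (!is.null(r$skipped)) list(skipped = r$skipped) else list(
          n_rsf_obs = r$rsf_fit$n_obs, rsf_aic = r$rsf_fit$aic,
          cv_mean_rho = r$cv$mean_rho
        )
      }),
      decisions = list(bandwidth = "reference (Silverman/Worton plug-in)",
                       isopleth_level = 0.99,
                       ratio = config$ratio %||% 16L)
    ), file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  })

  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
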
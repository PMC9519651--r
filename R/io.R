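#' Read a GPS relocation table
#'
#' CSV contract: columns `animal_id`, `timestamp` (ISO-8601 UTC), `x`, `y`
#' (projected meters), `sex`, `dop_ok`. Rows failing the fix-quality flag
#' are counted and dropped (the >= 4-satellite screen); rows are sorted by
#' animal and time; duplicate (animal, timestamp) pairs are an error.
#'
#' @param path CSV file path.
#' @return data.frame of relocations with `quality_ok = TRUE` throughout;
#'   the number of quality-dropped rows in `attr(, "n_quality_dropped")`.
#' @export
read_relocations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "timestamp", "x", "y", "sex", "dop_ok")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  raw <- as.character(df$timestamp)
  ts <- as.POSIXct(strptime(raw, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  fallback <- is.na(ts)
  ts[fallback] <- as.POSIXct(strptime(raw[fallback], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  if (anyNA(ts)) {
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(which(is.na(ts)), 5L), collapse = ", "))
  }
  df$timestamp <- ts
  dropped <- sum(!.as_flag(df$dop_ok))
  df <- df[.as_flag(df$dop_ok), , drop = FALSE]
  df <- df[order(df$animal_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[, c("animal_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate fix for animal '%s' at %s",
                 df$animal_id[i], format(df$timestamp[i], tz = "UTC")))
  }
  df$quality_ok <- TRUE
  df$dop_ok <- NULL
  rownames(df) <- NULL
  attr(df, "n_quality_dropped") <- dropped
  df
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a relocation table as CSV (ISO-8601 UTC timestamps)
#' @param relocations data.frame with a POSIXct `timestamp` column.
#' @param path output path.
#' @export
write_relocations_csv <- function(relocations, path) {
  out <- relocations
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (!is.null(out$quality_ok) && is.null(out$dop_ok)) {
    out$dop_ok <- out$quality_ok
    out$quality_ok <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read driven-hunt dates from CSV
#' @param path CSV with a `date` column (ISO-8601).
#' @return Date vector.
#' @export
read_hunts_csv <- function(path) {
  as.Date(utils::read.csv(path, stringsAsFactors = FALSE)$date)
}

#' Write a coefficient table and fit diagnostics
#'
#' CSV of (term, estimate, se, p) plus a JSON sidecar with variance
#' components, logLik, AIC and convergence info.
#'
#' @param fit a `fit_result`.
#' @param path_csv,path_json output paths.
#' @export
write_fit <- function(fit, path_csv, path_json) {
  utils::write.csv(fit$coefficients[, c("term", "estimate", "se", "p")],
                   path_csv, row.names = FALSE)
  jsonlite::write_json(list(
    re_sd = fit$re_sd, re_var = fit$re_var, logLik = fit$logLik,
    aic = fit$aic, n_obs = fit$n_obs, n_groups = fit$n_groups,
    nAGQ = fit$nAGQ, converged = fit$converged, messages = fit$messages
  ), path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}
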
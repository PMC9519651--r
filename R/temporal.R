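#' Assign 21-day treatment categories relative to grazing terms
#'
#' Each fix is labelled relative to the grazing terms of its site group:
#' \describe{
#'   \item{before}{the last 21 days preceding a term's start}
#'   \item{early}{days 1-21 of the term}
#'   \item{ongoing}{days 22-42 of the term, assigned only when the term is
#'     long enough to contain that full window (>= 42 days); a short term --
#'     such as a 25-day December term -- therefore yields only three labels}
#'   \item{after}{the first 21 days following the term's end}
#'   \item{unassigned}{everything else (including days 43+ of a long term)}
#' }
#' Windows are defined on local calendar dates (fixed UTC offset). If windows
#' of consecutive terms ever overlap, labels tied to an active term win over
#' before/after, and `after` wins over `before`.
#'
#' @param timestamps POSIXct (UTC) or Date vector.
#' @param schedule a `grazing_schedule`.
#' @param group site-group label whose terms apply to these fixes.
#' @param utc_offset hours added to UTC to obtain local calendar dates.
#' @return factor with levels before, early, ongoing, after, unassigned.
#' @export
assign_treatment <- function(timestamps, schedule, group, utc_offset = 1) {
  stopifnot(inherits(schedule, "grazing_schedule"))
  iv <- schedule$intervals[schedule$intervals$group == group, , drop = FALSE]
  if (nrow(iv) == 0L) stop(sprintf("no grazing intervals for group '%s'", group))
  dates <- .local_date(timestamps, utc_offset)
  # build labelled windows; precedence: early/ongoing (in-term) > after > before
  win <- list()
  for (k in seq_len(nrow(iv))) {
    s <- iv$start[k]; e <- iv$end[k]
    len <- as.numeric(e - s) + 1
    win[[length(win) + 1L]] <- list(lab = "before", a = s - 21L, b = s - 1L, prio = 1L)
    win[[length(win) + 1L]] <- list(lab = "early", a = s, b = min(s + 20L, e), prio = 3L)
    if (len >= 42) {
      win[[length(win) + 1L]] <- list(lab = "ongoing", a = s + 21L, b = s + 41L, prio = 3L)
    }
    win[[length(win) + 1L]] <- list(lab = "after", a = e + 1L, b = e + 21L, prio = 2L)
  }
  lab <- rep("unassigned", length(dates))
  prio <- rep(0L, length(dates))
  for (w in win) {
    hit <- dates >= w$a & dates <= w$b & w$prio > prio
    lab[hit] <- w$lab
    prio[hit] <- w$prio
  }
  factor(lab, levels = .treatment_levels)
}

.local_date <- function(timestamps, utc_offset) {
  if (inherits(timestamps, "Date")) return(timestamps)
  as.Date(as.POSIXct(timestamps, tz = "UTC") + utc_offset * 3600, tz = "UTC")
}

#' Exclude fixes recorded during driven hunts or the following six days
#'
#' Removes all relocations whose local calendar date falls on a hunt day or
#' any of the six subsequent days; windows of overlapping hunts are unioned.
#' The operation is idempotent and keeps remaining rows in order.
#'
#' @param relocations data.frame with a `timestamp` column (POSIXct UTC).
#' @param hunt_dates Date vector of driven-hunt days (may be empty).
#' @param utc_offset hours added to UTC for local dates.
#' @return the filtered data.frame; the number of removed rows is available
#'   as attribute `n_excluded`.
#' @export
exclude_hunt_windows <- function(relocations, hunt_dates, utc_offset = 1) {
  if (length(hunt_dates) == 0L) {
    attr(relocations, "n_excluded") <- 0L
    return(relocations)
  }
  hunt_dates <- as.Date(hunt_dates)
  banned <- unique(do.call(c, lapply(hunt_dates, function(d) d + 0:6)))
  dates <- .local_date(relocations$timestamp, utc_offset)
  keep <- !(dates %in% banned)
  out <- relocations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Flag calving and rutting periods
#'
#' Calving: 15 May to 15 June, females only. Rut: 1 September to 15 October,
#' both sexes.
#'
#' @param timestamps POSIXct (UTC) or Date vector.
#' @param sex character vector ("female"/"male"), recycled to length.
#' @param utc_offset hours added to UTC for local dates.
#' @return data.frame with logical columns `calving` and `rut`.
#' @export
flag_biological_periods <- function(timestamps, sex, utc_offset = 1) {
  dates <- .local_date(timestamps, utc_offset)
  sex <- rep_len(as.character(sex), length(dates))
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  calving_window <- (m == 5 & d >= 15) | (m == 6 & d <= 15)
  rut_window <- (m == 9) | (m == 10 & d <= 15)
  data.frame(calving = calving_window & sex == "female",
             rut = rut_window)
}

#' Assign the analysis season
#'
#' May-October is summer, November-January is winter, February-April is
#' excluded from the seasonal models.
#'
#' @param timestamps POSIXct (UTC) or Date vector.
#' @param utc_offset hours added to UTC for local dates.
#' @return factor with levels summer, winter, excluded.
#' @export
assign_season <- function(timestamps, utc_offset = 1) {
  m <- as.integer(format(.local_date(timestamps, utc_offset), "%m"))
  out <- rep("excluded", length(m))
  out[m >= 5 & m <= 10] <- "summer"
  out[m >= 11 | m == 1] <- "winter"
  factor(out, levels = .season_levels)
}
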
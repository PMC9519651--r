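#' Grazing schedule
#'
#' Dated grazing intervals per site group. Intervals are closed date ranges
#' (`start` and `end` are grazing days). Intervals within a site group must
#' not overlap.
#'
#' @param intervals data.frame with columns `site_id`, `group`, `start`,
#'   `end` (Date or ISO-8601 strings).
#' @return An object of class `grazing_schedule`.
#' @export
grazing_schedule <- function(intervals) {
  req <- c("site_id", "group", "start", "end")
  if (!all(req %in% names(intervals))) {
    stop("schedule needs columns: ", paste(req, collapse = ", "))
  }
  intervals$start <- as.Date(intervals$start)
  intervals$end <- as.Date(intervals$end)
  if (any(intervals$end < intervals$start)) stop("interval end before start")
  for (g in unique(intervals$group)) {
    iv <- intervals[intervals$group == g, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
      stop(sprintf("overlapping grazing intervals within group '%s'", g))
    }
  }
  intervals <- intervals[order(intervals$group, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals), class = "grazing_schedule")
}

#' @export
print.grazing_schedule <- function(x, ...) {
  cat(sprintf("<grazing_schedule> %d interval(s), groups: %s\n",
              nrow(x$intervals), paste(unique(x$intervals$group), collapse = ", ")))
  print(x$intervals)
  invisible(x)
}

#' Generate a grazing schedule emulating the study pattern
#'
#' The study's herded flock grazed a short winter term in December of the
#' first year (about 25 days) and long summer terms in later years, starting
#' in June and lasting until September or October, alternating between the
#' northern site group and the southern one within each summer.
#'
#' @param sites a `site_set`; its `group` labels define the site groups.
#' @param years integer vector of calendar years. The smallest year receives
#'   the December term; all later years receive summer terms.
#' @param seed integer seed (start days jitter by a few days between years).
#' @return a `grazing_schedule`.
#' @export
generate_schedule <- function(sites, years, seed = 1L) {
  stopifnot(inherits(sites, "site_set"))
  groups <- unique(sites$group)
  with_seed(seed, {
    rows <- list()
    years <- sort(unique(as.integer(years)))
    for (i in seq_along(years)) {
      y <- years[i]
      if (i == 1L) {
        # short winter term: ~25 days in December, one site group
        start <- as.Date(sprintf("%d-12-%02d", y, sample(1:5, 1L)))
        g <- groups[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = paste(sites$site_id[sites$group == g], collapse = "+"),
          group = g, start = start, end = start + 24L
        )
      } else {
        # summer term June -> September/October, split across site groups
        start <- as.Date(sprintf("%d-06-%02d", y, sample(1:10, 1L)))
        end <- as.Date(sprintf("%d-%02d-%02d", y, sample(9:10, 1L), sample(5:25, 1L)))
        if (length(groups) > 1L) {
          mid <- start + floor(as.numeric(end - start) / 2)
          ord <- if (i %% 2L == 0L) groups[1:2] else groups[2:1]
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = paste(sites$site_id[sites$group == ord[1L]], collapse = "+"),
            group = ord[1L], start = start, end = mid
          )
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = paste(sites$site_id[sites$group == ord[2L]], collapse = "+"),
            group = ord[2L], start = mid + 1L, end = end
          )
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = paste(sites$site_id, collapse = "+"),
            group = groups[1L], start = start, end = end
          )
        }
      }
    }
    grazing_schedule(do.call(rbind, rows))
  })
}

#' Generate driven-hunt dates
#'
#' Two driven hunts per winter, as in the study area's hunting regime: one in
#' November and one in January of the following year.
#'
#' @param years integer vector of calendar years.
#' @param seed integer seed.
#' @return Date vector of hunt days.
#' @export
generate_hunts <- function(years, seed = 1L) {
  with_seed(seed, {
    out <- as.Date(character(0))
    for (y in sort(unique(as.integer(years)))) {
      out <- c(out,
               as.Date(sprintf("%d-11-%02d", y, sample(5:25, 1L))),
               as.Date(sprintf("%d-01-%02d", y + 1L, sample(5:25, 1L))))
    }
    sort(out)
  })
}

#' Write a grazing schedule as CSV
#' @param schedule a `grazing_schedule`.
#' @param path output path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$intervals, path, row.names = FALSE)
  invisible(path)
}

#' Read a grazing schedule from CSV
#' @param path CSV with columns site_id, group, start, end.
#' @return a `grazing_schedule`.
#' @export
read_schedule_csv <- function(path) {
  grazing_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}
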
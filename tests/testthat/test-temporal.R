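test_that("21-day treatment windows around a long summer term", {
  sch <- toy_schedule()  # summer term 2017-07-01 .. 2017-09-30
  lab <- function(d) as.character(assign_treatment(as.Date(d), sch, "north",
                                                   utc_offset = 0))
  expect_equal(lab("2017-06-15"), "before")
  expect_equal(lab("2017-06-10"), "before")   # start - 21
  expect_equal(lab("2017-06-09"), "unassigned")
  expect_equal(lab("2017-07-10"), "early")
  expect_equal(lab("2017-07-21"), "early")    # day 21
  expect_equal(lab("2017-07-22"), "ongoing")  # day 22
  expect_equal(lab("2017-08-05"), "ongoing")
  expect_equal(lab("2017-08-11"), "ongoing")  # day 42
  expect_equal(lab("2017-08-12"), "unassigned")  # day 43+ of a long term
  expect_equal(lab("2017-10-05"), "after")
  expect_equal(lab("2017-10-21"), "after")    # end + 21
  expect_equal(lab("2017-10-22"), "unassigned")
})

test_that("a 25-day December term yields only three labels", {
  sch <- toy_schedule()
  days <- seq(as.Date("2016-10-25"), as.Date("2017-02-15"), by = "day")
  tr <- assign_treatment(days, sch, "north", utc_offset = 0)
  tab <- table(tr)
  expect_equal(unname(tab[["before"]]), 21L)
  expect_equal(unname(tab[["early"]]), 21L)
  expect_equal(unname(tab[["ongoing"]]), 0L)
  expect_equal(unname(tab[["after"]]), 21L)
})

test_that("each fix gets exactly one label and windows are disjoint", {
  sch <- toy_schedule()
  days <- seq(as.Date("2016-10-01"), as.Date("2017-12-31"), by = "day")
  tr <- assign_treatment(days, sch, "north", utc_offset = 0)
  expect_equal(length(tr), length(days))
  expect_false(anyNA(tr))
  # windows of different labels never share a day: labels per day are unique
  expect_equal(nrow(unique(data.frame(d = days, t = tr))), length(days))
})

test_that("overlapping grazing intervals within a group are rejected", {
  expect_error(grazing_schedule(data.frame(
    site_id = c("a", "a"), group = c("g", "g"),
    start = c("2017-06-01", "2017-06-20"), end = c("2017-06-25", "2017-07-10")
  )), "overlapping")
})

test_that("hunt exclusion removes the hunt day plus six days, idempotently", {
  rel <- data.frame(
    timestamp = as.POSIXct(paste0("2017-11-", sprintf("%02d", 1:20), " 12:00:00"),
                           tz = "UTC")
  )
  out <- exclude_hunt_windows(rel, as.Date("2017-11-05"), utc_offset = 0)
  kept <- as.integer(format(as.Date(out$timestamp), "%d"))
  expect_equal(kept, c(1:4, 12:20))
  expect_equal(attr(out, "n_excluded"), 7L)
  # idempotence
  again <- exclude_hunt_windows(out, as.Date("2017-11-05"), utc_offset = 0)
  expect_equal(again$timestamp, out$timestamp)
  expect_equal(attr(again, "n_excluded"), 0L)
  # empty hunt list is the identity
  id <- exclude_hunt_windows(rel, as.Date(character(0)))
  expect_equal(nrow(id), 20L)
})

test_that("overlapping hunt windows are unioned without double counting", {
  rel <- data.frame(
    timestamp = as.POSIXct(paste0("2017-11-", sprintf("%02d", 1:25), " 12:00:00"),
                           tz = "UTC")
  )
  out <- exclude_hunt_windows(rel, as.Date(c("2017-11-05", "2017-11-08")),
                              utc_offset = 0)
  # brute-force day set: union of 5..11 and 8..14
  banned <- union(5:11, 8:14)
  expect_equal(as.integer(format(as.Date(out$timestamp), "%d")),
               setdiff(1:25, banned))
})

test_that("calving and rut flags follow the calendar windows and sex", {
  f <- flag_biological_periods(as.Date("2017-06-01"), "female", utc_offset = 0)
  expect_true(f$calving)
  m <- flag_biological_periods(as.Date("2017-06-01"), "male", utc_offset = 0)
  expect_false(m$calving)
  expect_true(flag_biological_periods(as.Date("2017-09-20"), "male", 0)$rut)
  expect_true(flag_biological_periods(as.Date("2017-09-20"), "female", 0)$rut)
  expect_false(flag_biological_periods(as.Date("2017-10-16"), "female", 0)$rut)
  expect_true(flag_biological_periods(as.Date("2017-05-15"), "female", 0)$calving)
  expect_false(flag_biological_periods(as.Date("2017-05-14"), "female", 0)$calving)
  expect_true(flag_biological_periods(as.Date("2017-10-15"), "male", 0)$rut)
})

test_that("season assignment splits the year May-Oct / Nov-Jan / rest", {
  expect_equal(as.character(assign_season(as.Date("2017-07-15"), 0)), "summer")
  expect_equal(as.character(assign_season(as.Date("2017-12-15"), 0)), "winter")
  expect_equal(as.character(assign_season(as.Date("2018-01-20"), 0)), "winter")
  expect_equal(as.character(assign_season(as.Date("2017-03-15"), 0)), "excluded")
  days <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  tab <- table(assign_season(days, 0))
  expect_equal(unname(tab[["summer"]]), as.integer(sum(days >= "2017-05-01" & days <= "2017-10-31")))
  expect_equal(unname(tab[["excluded"]]), as.integer(sum(days >= "2017-02-01" & days <= "2017-04-30")))
})

test_that("local-date treatment labelling respects the UTC offset", {
  sch <- toy_schedule()
  # 23:30 UTC on 30 June is 00:30 local (+1): first day of the term
  ts <- as.POSIXct("2017-06-30 23:30:00", tz = "UTC")
  expect_equal(as.character(assign_treatment(ts, sch, "north", utc_offset = 1)),
               "early")
  expect_equal(as.character(assign_treatment(ts, sch, "north", utc_offset = 0)),
               "before")
})
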
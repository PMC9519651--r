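test_that("generated schedules emulate the study pattern", {
  sites <- toy_sites()
  sch <- generate_schedule(sites, 2016:2018, seed = 1)
  iv <- sch$intervals
  # first year: one ~25-day December term
  dec <- iv[format(iv$start, "%Y") == "2016", ]
  expect_equal(nrow(dec), 1L)
  expect_equal(format(dec$start, "%m"), "12")
  expect_equal(as.numeric(dec$end - dec$start) + 1, 25)
  # later years: summer terms starting in June, ending September/October
  s17 <- iv[format(iv$start, "%Y") == "2017", ]
  expect_equal(format(min(s17$start), "%m"), "06")
  expect_true(format(max(s17$end), "%m") %in% c("09", "10"))
  # intervals within each group sorted and disjoint
  for (g in unique(iv$group)) {
    gi <- iv[iv$group == g, ]
    expect_false(is.unsorted(gi$start))
    if (nrow(gi) > 1L) {
      expect_true(all(gi$start[-1L] > gi$end[-nrow(gi)]))
    }
  }
  # determinism
  expect_identical(generate_schedule(sites, 2016:2018, seed = 1)$intervals, iv)
  expect_error(generate_schedule(site_set(list(unit_square))[c()], 2016, 1))
})

test_that("simulated fixes are spaced exactly two hours apart", {
  study <- reference_study(seed = 2, extent = 4000, cell = 40, years = 2017L)
  truth <- true_model(c(dist = -0.5), re_sd = 0.5,
                      scaling = list(dist = list(mean = 1200, sd = 700),
                                     cover = list(mean = 50, sd = 25),
                                     ndvi = list(mean = 0.35, sd = 0.22)))
  home <- cbind(c(400, 3600, 3600, 400), c(400, 400, 3600, 3600))
  rel <- simulate_deer(truth, study, home, 200,
                       start = as.POSIXct("2017-06-01 00:00:00", tz = "UTC"),
                       seed = 3)
  expect_equal(unique(diff(as.numeric(rel$timestamp))), 7200)
  expect_equal(nrow(rel), 200L)
  # determinism
  rel2 <- simulate_deer(truth, study, home, 200,
                        start = as.POSIXct("2017-06-01 00:00:00", tz = "UTC"),
                        seed = 3)
  expect_identical(rel$x, rel2$x)
})

test_that("null selection model gives uniform use over the home polygon", {
  study <- reference_study(seed = 2, extent = 4000, cell = 40, years = 2017L)
  truth <- true_model(c(dist = 0), re_sd = 0.5,
                      scaling = list(dist = list(mean = 1200, sd = 700),
                                     cover = list(mean = 50, sd = 25),
                                     ndvi = list(mean = 0.35, sd = 0.22)))
  home <- cbind(c(200, 3000, 3000, 200), c(200, 200, 2600, 2600))
  rel <- simulate_deer(truth, study, home, 5000,
                       start = as.POSIXct("2017-02-01 00:00:00", tz = "UTC"),
                       seed = 9)
  # 2-D goodness-of-fit: chi-square over a 5x5 grid of equal-area cells
  bx <- cut(rel$x, seq(200, 3000, length.out = 6))
  by <- cut(rel$y, seq(200, 2600, length.out = 6))
  p <- suppressWarnings(chisq.test(table(bx, by))$p.value)
  # independence test is not exactly uniformity; use cell counts directly
  counts <- table(bx, by)
  p_unif <- suppressWarnings(chisq.test(as.vector(counts),
                                        p = rep(1 / 25, 25))$p.value)
  expect_gt(p_unif, 0.01)
})

test_that("negative distance selection pulls fixes toward the sites", {
  study <- reference_study(seed = 2, extent = 4000, cell = 40, years = 2017L)
  truth <- true_model(c(dist = -0.8), re_sd = 0,
                      scaling = list(dist = list(mean = 1200, sd = 700),
                                     cover = list(mean = 50, sd = 25),
                                     ndvi = list(mean = 0.35, sd = 0.22)))
  home <- cbind(c(200, 3800, 3800, 200), c(200, 200, 3800, 3800))
  rel <- simulate_deer(truth, study, home, 10000,
                       start = as.POSIXct("2017-02-01 00:00:00", tz = "UTC"),
                       seed = 10)
  unif <- sample_in_polygon(10000, home, seed = 11)
  d_sel <- mean(distance_to_sites(rel[, c("x", "y")], study$sites))
  d_unif <- mean(distance_to_sites(unif, study$sites))
  expect_lt(d_sel, d_unif)
})

test_that("binary use series follows the inverse-logit of its coefficients", {
  sch <- toy_schedule()
  ts <- rep(as.POSIXct("2017-07-05 00:00:00", tz = "UTC") + 7200 * (0:430),
            length.out = 1e4)  # inside labelled windows
  # intercept 0: frequency ~ 0.5
  y0 <- simulate_use_series(c("(Intercept)" = 0), sch, ts, seed = 1,
                            group = "north")
  expect_lt(abs(mean(y0) - 0.5), 0.02)
  # determinism
  y0b <- simulate_use_series(c("(Intercept)" = 0), sch, ts, seed = 1,
                             group = "north")
  expect_identical(y0, y0b)
  # timestamps outside coverage are an error
  far <- as.POSIXct("2018-03-01 12:00:00", tz = "UTC")
  expect_error(simulate_use_series(c("(Intercept)" = 0), sch, far, 1, "north"),
               "outside schedule")
  expect_error(simulate_use_series(c(todnight = 1), sch, ts, 1, "north"),
               "intercept")
})

test_that("use-series frequency matches the closed form at a strong intercept", {
  # inverse-logit of -4.6966 = 0.0090...
  sch <- toy_schedule()
  ts <- rep(as.POSIXct("2017-07-05 12:00:00", tz = "UTC"), 1e5) + 7200
  y <- simulate_use_series(c("(Intercept)" = -4.6966), sch, ts, seed = 2,
                           group = "north")
  expect_lt(abs(mean(y) - plogis(-4.6966)), 0.003)
  expect_equal(plogis(-4.6966), 0.0090, tolerance = 0.01)
})

test_that("true_model validates its coefficient vocabulary", {
  expect_error(true_model(c(1, 2)), "named")
  expect_error(true_model(c(banana = 1)), "unknown design term")
  expect_error(true_model(c(dist = Inf)), "finite")
  tm <- true_model(c(dist = -0.5, `dist:treatmentearly` = 0.3))
  expect_s3_class(tm, "true_model")
})
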
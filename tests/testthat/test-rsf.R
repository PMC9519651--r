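mock_fit <- function(terms_df, terms = NULL, xlevels = NULL, scaling = NULL) {
  structure(list(coefficients = terms_df, terms = terms, xlevels = xlevels,
                 scaling = scaling), class = "fit_result")
}

default_scaling <- list(cover = list(mean = 50, sd = 25),
                        ndvi = list(mean = 0.35, sd = 0.22),
                        dist = list(mean = 1500, sd = 900))

test_that("RSF retains exactly the significant non-intercept coefficients", {
  cf <- data.frame(
    term = c("(Intercept)", "dist", "dist2", "dist:treatmentearly"),
    estimate = c(-2.5, -0.38, -0.11, -0.02),
    se = c(0.03, 0.02, 0.01, 0.03),
    p = c(1e-10, 1e-10, 1e-10, 0.4928)
  )
  fit <- mock_fit(cf, scaling = default_scaling)
  rsf <- build_rsf(fit)
  expect_named(rsf$coefficients, c("dist", "dist2"))
  expect_false("(Intercept)" %in% names(rsf$coefficients))
  expect_false("dist:treatmentearly" %in% names(rsf$coefficients))
  # alpha = 1 keeps every non-intercept coefficient
  rsf_all <- build_rsf(fit, alpha = 1)
  expect_named(rsf_all$coefficients, c("dist", "dist2", "dist:treatmentearly"))
  cf$p <- rep(0.9, 4)
  expect_error(build_rsf(mock_fit(cf)), "no significant")
})

test_that("RSF score is exp of the retained linear predictor", {
  cf <- data.frame(term = c("(Intercept)", "dist"),
                   estimate = c(-2.5, -0.383457), se = c(0.1, 0.02),
                   p = c(1e-9, 1e-9))
  rsf <- build_rsf(mock_fit(cf, scaling = default_scaling))
  # scaled dist = 1  <=>  raw = mean + sd
  s <- rsf_score(rsf, data.frame(dist_raw = 1500 + 900))
  expect_equal(s, exp(-0.383457), tolerance = 1e-12)
  # all covariates at scaled zero, reference scenario: w = exp(0) = 1
  s0 <- rsf_score(rsf, data.frame(dist_raw = 1500))
  expect_equal(s0, 1)
  # strictly positive scores
  s_many <- rsf_score(rsf, data.frame(dist_raw = runif(100, 0, 5000)))
  expect_true(all(s_many > 0))
})

test_that("dummy and interaction expansion matches the design matrix", {
  cf <- data.frame(
    term = c("dist", "treatmentearly", "todnight", "dist:treatmentearly"),
    estimate = c(-0.5, 0.2, 0.1, 0.3), se = rep(0.01, 4), p = rep(1e-9, 4)
  )
  rsf <- build_rsf(mock_fit(cf, scaling = default_scaling))
  z <- 0.8
  raw <- 1500 + 900 * z
  w <- rsf_score(rsf, data.frame(dist_raw = raw),
                 scenario = list(treatment = "early", tod = "night"))
  expect_equal(w, exp(-0.5 * z + 0.2 + 0.1 + 0.3 * z), tolerance = 1e-12)
  w_ref <- rsf_score(rsf, data.frame(dist_raw = raw),
                     scenario = list(treatment = "before", tod = "day"))
  expect_equal(w_ref, exp(-0.5 * z), tolerance = 1e-12)
})

test_that("prediction maps respect monotonicity and missing cells", {
  study <- reference_study(seed = 2, extent = 2000, cell = 50, years = 2017L)
  cf <- data.frame(term = "dist", estimate = -0.6, se = 0.01, p = 1e-9)
  rsf <- build_rsf(mock_fit(cf, scaling = default_scaling))
  m <- predict_map(rsf, study$cover, study$ndvi, study$sites)
  d <- distance_to_sites(raster_cells(study$cover), study$sites)
  # monotone non-increasing with distance
  expect_lt(cor(as.vector(m$z), d), 0)
  ord <- order(d)
  expect_true(all(diff(as.vector(m$z)[ord]) <= 1e-12))
  # per-cell score equals rsf_score at that cell
  pts <- data.frame(dist_raw = d[100])
  expect_equal(as.vector(m$z)[100], rsf_score(rsf, pts))
  # a missing NDVI cell propagates when the model uses NDVI
  cf2 <- data.frame(term = c("dist", "ndvi"), estimate = c(-0.6, 0.2),
                    se = c(0.01, 0.01), p = c(1e-9, 1e-9))
  rsf2 <- build_rsf(mock_fit(cf2, scaling = default_scaling))
  ndvi_na <- study$ndvi
  ndvi_na$z[3, 4] <- NA
  m2 <- predict_map(rsf2, study$cover, ndvi_na, study$sites)
  expect_true(is.na(m2$z[3, 4]))
  expect_false(anyNA(m2$z[-c(3 + (4 - 1) * m2$nx)]))
})

test_that("scenario ratio is constant where no interaction involves distance", {
  cf <- data.frame(term = c("dist", "treatmentongoing"),
                   estimate = c(-0.4, 0.7), se = c(0.01, 0.01), p = c(1e-9, 1e-9))
  rsf <- build_rsf(mock_fit(cf, scaling = default_scaling))
  pts <- data.frame(dist_raw = runif(50, 0, 4000))
  r <- rsf_score(rsf, pts, scenario = list(treatment = "ongoing")) /
    rsf_score(rsf, pts, scenario = list(treatment = "before"))
  expect_equal(r, rep(exp(0.7), 50), tolerance = 1e-12)
})

test_that("relative scores divide by the scenario median", {
  s <- c(1, 2, 3, 4, 5)
  rs <- relative_scores(s, rep("a", 5))
  expect_equal(rs, s / 3)
  expect_equal(median(rs), 1)
  # constant scores map to 1
  expect_equal(relative_scores(rep(4, 7), rep("b", 7)), rep(1, 7))
  # scaling preserves ratios within a scenario
  two <- relative_scores(c(s, 10 * s), rep(c("a", "b"), each = 5))
  expect_equal(two[1:4] / two[2:5], s[1:4] / s[2:5])
  expect_equal(two[6:10], s / 3)
  expect_error(relative_scores(c(NA_real_, NA_real_), c("a", "a")), "missing")
})

test_that("score-distance profiles move the selection peak between scenarios", {
  cf <- data.frame(
    term = c("dist", "dist2", "dist:treatmentongoing"),
    estimate = c(-0.6, -0.35, 0.6), se = rep(0.01, 3), p = rep(1e-9, 3)
  )
  rsf <- build_rsf(mock_fit(cf, scaling = default_scaling))
  prof <- score_distance_profile(rsf, seq(0, 4500, by = 50),
                                 scenarios = list(before = list(treatment = "before"),
                                                  ongoing = list(treatment = "ongoing")))
  peak <- vapply(split(prof, prof$scenario),
                 function(d) d$distance[which.max(d$score)], numeric(1))
  # analytic peaks: z* = -b1/(2 b2) on the scaled axis
  expect_equal(unname(peak["before"]), 1500 - 0.857 * 900, tolerance = 60)
  expect_equal(unname(peak["ongoing"]), 1500, tolerance = 60)
  expect_gt(peak["ongoing"], peak["before"])
})
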
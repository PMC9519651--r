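test_that("binned rho is 1 for perfect ranking and -1 for inverted ranking", {
  # used density increasing in score: adjusted frequency strictly
  # increasing across the availability-quantile bins
  set.seed(50)
  avail <- runif(20000)
  used <- sqrt(runif(5000))
  expect_equal(cv_rho(c(used, avail), c(rep(1, 5000), rep(0, 20000))), 1.0)
  # inverted relation
  used_lo <- 1 - sqrt(runif(5000))
  expect_equal(cv_rho(c(used_lo, avail), c(rep(1, 5000), rep(0, 20000))), -1.0)
})

test_that("monotone score-response relations give monotone adjusted frequencies", {
  set.seed(51)
  avail <- rnorm(5000)
  used <- rnorm(1000, mean = 1.2)  # stochastically larger
  rho <- cv_rho(c(used, avail), c(rep(1, 1000), rep(0, 5000)))
  expect_gt(rho, 0.8)
})

test_that("cross-validation scored by the generating model ranks well", {
  cvd <- cv_dataset(seed = 5, n_animals = 5, n_fixes = 500, ratio = 4)
  cv <- kfold_cv(cvd$data, k = 5, seed = 1, score_fun = truth_scorer(cvd$truth))
  expect_equal(nrow(cv$folds), 5L)
  expect_gt(cv$mean_rho, 0.9)
})

test_that("random scores give small absolute rho on average", {
  cvd <- cv_dataset(seed = 6, n_animals = 5, n_fixes = 500, ratio = 4)
  rhos <- vapply(1:20, function(s) {
    kfold_cv(cvd$data, k = 5, seed = s,
             score_fun = function(df) {
               set.seed(1000 + s)
               runif(nrow(df))
             })$mean_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.5)
})

test_that("per-fold refits validate an informative RSF on held-out data", {
  cvd <- cv_dataset(seed = 7, n_animals = 5, n_fixes = 400, ratio = 4)
  cv <- kfold_cv(cvd$data, terms = c("cover", "cover2", "ndvi", "dist"),
                 k = 3, seed = 2, alpha = 1, nAGQ = 1)
  expect_gt(cv$mean_rho, 0.5)
})

test_that("blocked folds hold out whole animals; random folds keep all animals", {
  cvd <- cv_dataset(seed = 8, n_animals = 6, n_fixes = 200, ratio = 4)
  dat <- cvd$data
  scorer <- truth_scorer(cvd$truth)
  cvb <- kfold_cv(dat, k = 3, blocking = "by_animal", seed = 3, score_fun = scorer)
  expect_equal(nrow(cvb$folds), 3L)
  expect_error(kfold_cv(dat, k = 10, blocking = "by_animal", seed = 3,
                        score_fun = scorer), ">= k animals")
  expect_error(kfold_cv(dat, k = 1, score_fun = scorer), "k must be")
})

test_that("blocked rho does not beat random rho under animal heterogeneity", {
  # animals with idiosyncratic cover preference: transferability across
  # animals (blocked CV) should on average be no better than random CV
  diffs <- vapply(1:20, function(s) {
    study <- reference_study(seed = 2, extent = 4000, cell = 40, years = 2017L)
    home <- cbind(c(200, 3800, 3800, 200), c(200, 200, 3800, 3800))
    scaling <- list(dist = list(mean = 1200, sd = 700),
                    cover = list(mean = 50, sd = 25),
                    ndvi = list(mean = 0.35, sd = 0.22))
    rel <- lapply(1:5, function(i) {
      slope <- grazeRSF:::with_seed(7000 + 10L * s + i, rnorm(1, 0.6, 1.2))
      tm <- true_model(c(cover = slope, ndvi = 0.4), re_sd = 0, scaling = scaling)
      simulate_deer(tm, study, home, 220,
                    start = as.POSIXct("2017-03-01 00:00:00", tz = "UTC"),
                    animal_id = sprintf("a%d", i), seed = 900 + 10L * s + i)
    })
    rel <- do.call(rbind, rel)
    rel$response <- 1
    iso <- isopleth_polygon(kde_surface(rel[, c("x", "y")], bandwidth = 150,
                                        cell_m = 40), 0.99)
    av <- sample_available(iso, rel, ratio = 4, seed = 800 + s)
    dat <- attach_covariates(rbind(rel, av[names(rel)]),
                             study$cover, study$ndvi, study$sites)
    dat <- dat[complete.cases(dat[, c("cover_raw", "ndvi_raw", "dist_raw")]), ]
    prep <- prepare_model_data(dat, scaling = scaling)
    r_rand <- kfold_cv(prep, terms = c("cover", "ndvi"), k = 5, seed = s,
                       alpha = 1, nAGQ = 1)$mean_rho
    r_blk <- kfold_cv(prep, terms = c("cover", "ndvi"), k = 5,
                      blocking = "by_animal", seed = s, alpha = 1,
                      nAGQ = 1)$mean_rho
    r_blk - r_rand
  }, numeric(1))
  expect_lte(mean(diffs), 0)
})

test_that("recovery report compares shared terms with |z| and sign agreement", {
  tm <- true_model(c(dist = -0.5, dist2 = -0.2),
                   scaling = list(dist = list(mean = 0, sd = 1)))
  cf <- data.frame(term = c("(Intercept)", "dist", "dist2"),
                   estimate = c(-2, -0.5, -0.2), se = c(0.1, 0.05, 0.02),
                   p = c(0, 0, 0))
  fit <- structure(list(coefficients = cf), class = "fit_result")
  rep <- recovery_report(tm, fit)
  expect_equal(rep$term, c("dist", "dist2"))
  expect_equal(rep$diff, c(0, 0))
  expect_equal(rep$z, c(0, 0))
  expect_true(all(rep$sign_agree))
  expect_type(rep$sign_agree, "logical")
  tm2 <- true_model(c(cover = 1), scaling = NULL)
  expect_error(recovery_report(tm2, fit), "share no terms")
})
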
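# Shared fixtures and independent oracles for the test suite.

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

toy_sites <- function(extent = 6000) {
  grazeRSF:::.default_sites(extent)
}

# one long summer term plus the short December term, fixed dates
toy_schedule <- function() {
  grazing_schedule(data.frame(
    site_id = c("N1", "N1"), group = c("north", "north"),
    start = c("2016-12-01", "2017-07-01"),
    end = c("2016-12-25", "2017-09-30"),
    stringsAsFactors = FALSE
  ))
}

# ---- independent GLMM oracle: fixed-grid quadrature + iterated grid search

oracle_marginal_ll <- function(beta, sigma, X, y, g, ngrid = 4001, width = 8) {
  u <- seq(-width, width, length.out = ngrid) * max(sigma, 0.25)
  du <- u[2L] - u[1L]
  total <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    eta <- outer(as.numeric(X[idx, , drop = FALSE] %*% beta), u, "+")
    lp <- colSums(stats::dbinom(y[idx], 1, stats::plogis(eta), log = TRUE))
    m <- max(lp)
    total <- total + m + log(sum(exp(lp - m) * stats::dnorm(u, 0, sigma)) * du)
  }
  total
}

oracle_fit_2par <- function(X, y, g) {
  ctr <- c(0, 0, 0.6)
  hw <- c(2.5, 2.5, 0.55)
  best <- -Inf
  bestpar <- ctr
  for (it in 1:12) {
    for (a in seq(ctr[1] - hw[1], ctr[1] + hw[1], length.out = 7)) {
      for (b in seq(ctr[2] - hw[2], ctr[2] + hw[2], length.out = 7)) {
        for (s in seq(max(ctr[3] - hw[3], 1e-3), ctr[3] + hw[3], length.out = 7)) {
          ll <- oracle_marginal_ll(c(a, b), s, X, y, g)
          if (ll > best) {
            best <- ll
            bestpar <- c(a, b, s)
          }
        }
      }
    }
    ctr <- bestpar
    hw <- hw / 2
  }
  list(logLik = best, par = bestpar)
}

# deterministic 20-observation, 2-group mixed-logistic fixture
glmm_fixture <- function() {
  g <- factor(rep(c("g1", "g2"), each = 10L))
  x <- rep(seq(-1.5, 1.5, length.out = 10L), 2L)
  y <- c(0, 1, 0, 0, 1, 0, 1, 1, 0, 1,
         1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  list(X = cbind("(Intercept)" = 1, x = x), y = y, g = g)
}

# ---- memoised end-to-end recovery fixture (shared across test files)

.fixture_env <- new.env(parent = emptyenv())

acceptance_recovery <- function() {
  if (is.null(.fixture_env$recovery)) {
    .fixture_env$recovery <- recovery_run(seed = 1L)
  }
  .fixture_env$recovery
}

# small labelled dataset simulated from an environment-only RSF truth, for
# cross-validation checks; scored either by the generating model or randomly
cv_dataset <- function(seed = 1L, n_animals = 5L, n_fixes = 500L, ratio = 4L) {
  study <- reference_study(seed = 2L, extent = 4000, cell = 40, years = 2017L)
  truth <- true_model(
    c(cover = 0.5, cover2 = -0.4, ndvi = 0.6, dist = -0.5),
    re_sd = 0,
    scaling = list(dist = list(mean = 1200, sd = 700),
                   cover = list(mean = 50, sd = 25),
                   ndvi = list(mean = 0.35, sd = 0.22))
  )
  home <- cbind(c(200, 3800, 3800, 200), c(200, 200, 3800, 3800))
  rel <- lapply(seq_len(n_animals), function(i) {
    simulate_deer(truth, study, home, n_fixes,
                  start = as.POSIXct("2017-03-01 00:00:00", tz = "UTC"),
                  animal_id = sprintf("a%02d", i), seed = seed + i)
  })
  rel <- do.call(rbind, rel)
  rel$response <- 1
  iso <- isopleth_polygon(kde_surface(rel[, c("x", "y")], bandwidth = 150,
                                      cell_m = 40), 0.99)
  av <- sample_available(iso, rel, ratio = ratio, seed = seed + 50L)
  dat <- rbind(rel, av[names(rel)])
  dat <- attach_covariates(dat, study$cover, study$ndvi, study$sites)
  dat <- dat[stats::complete.cases(dat[, c("cover_raw", "ndvi_raw", "dist_raw")]), ]
  prep <- prepare_model_data(dat, scaling = truth$scaling)
  list(data = prep, truth = truth)
}

# RSF scorer from a true model (for scoring held-out data by the truth)
truth_scorer <- function(truth) {
  rsf <- structure(list(coefficients = truth$coefficients,
                        scaling = truth$scaling, alpha = NA),
                   class = "rsf_model")
  function(df) rsf_score(rsf, df)
}
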
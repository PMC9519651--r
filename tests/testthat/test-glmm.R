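test_that("design matrix dummy-codes against the stated reference levels", {
  df <- data.frame(
    response = rep(0:1, 30),
    animal_id = rep(c("a", "b"), each = 30),
    tod = factor(rep(c("day", "night", "twilight"), 20), levels = c("day", "night", "twilight")),
    treatment = factor(rep(c("before", "early", "ongoing", "after"), 15),
                       levels = c("before", "early", "ongoing", "after")),
    dist = rnorm(60)
  )
  d <- build_design(df, c("tod"))
  expect_equal(colnames(d$X), c("(Intercept)", "todnight", "todtwilight"))
  d2 <- build_design(df, c("treatment", "tod", "treatment:tod"))
  # (4-1)*(3-1) = 6 interaction columns
  expect_equal(sum(d2$term_of_col == "treatment:tod"), 6L)
  # identical input gives identical column order
  d3 <- build_design(df, c("treatment", "tod", "treatment:tod"))
  expect_identical(colnames(d2$X), colnames(d3$X))
  expect_error(build_design(df, "nonexistent"), "unknown term")
  # absent factor level is dropped with a warning
  df2 <- df[df$treatment != "ongoing", ]
  expect_warning(d4 <- build_design(df2, "treatment"), "absent")
  expect_false("treatmentongoing" %in% colnames(d4$X))
})

test_that("mixed fit recovers a null-variance intercept model", {
  set.seed(41)
  n <- 1e4
  y <- rbinom(n, 1, 0.25)
  g <- factor(rep(1:5, length.out = n))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_mixed_logistic(X, y, g, nAGQ = 9)
  expect_lt(abs(f$coefficients$estimate - qlogis(0.25)), 0.1)
  expect_lt(f$re_var, 0.01)
  # AIC arithmetic identity
  expect_equal(f$aic, -2 * f$logLik + 2 * (ncol(X) + 1))
})

test_that("marginal log-likelihood matches the brute-force quadrature oracle", {
  fx <- glmm_fixture()
  f <- fit_mixed_logistic(fx$X, fx$y, fx$g, nAGQ = 25)
  orc <- oracle_fit_2par(fx$X, fx$y, fx$g)
  expect_lt(abs(f$logLik - orc$logLik), 1e-4)
})

test_that("with zero random-effect variance the fit matches the IRLS oracle", {
  set.seed(42)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.7 * x))
  g <- factor(rep(1:4, length.out = n))  # grouping carries no signal
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fit_mixed_logistic(X, y, g, nAGQ = 9)
  irls <- glm.fit(X, y, family = binomial())
  expect_lt(max(abs(f$coefficients$estimate - irls$coefficients)), 1e-4)
})

test_that("random-intercept SD is recovered from clustered data", {
  set.seed(43)
  G <- 50
  m <- 200
  b <- rnorm(G, 0, 1)
  g <- factor(rep(seq_len(G), each = m))
  x <- rnorm(G * m)
  y <- rbinom(G * m, 1, plogis(-0.5 + 0.8 * x + b[as.integer(g)]))
  f <- fit_mixed_logistic(cbind("(Intercept)" = 1, x = x), y, g, nAGQ = 9)
  expect_gt(f$re_sd, 0.7)
  expect_lt(f$re_sd, 1.3)
})

test_that("quadrature is stable between 9 and 25 nodes", {
  fx <- glmm_fixture()
  f9 <- fit_mixed_logistic(fx$X, fx$y, fx$g, nAGQ = 9)
  f25 <- fit_mixed_logistic(fx$X, fx$y, fx$g, nAGQ = 25)
  expect_lt(abs(f9$logLik - f25$logLik), 1e-3)
})

test_that("fit guards: constant response, single group, separation warning", {
  fx <- glmm_fixture()
  expect_error(fit_mixed_logistic(fx$X, rep(1, 20), fx$g), "constant response")
  expect_error(fit_mixed_logistic(fx$X, fx$y, factor(rep("a", 20))), "2 groups")
  # quasi-separated fixture: x separates y perfectly within huge-effect data
  set.seed(44)
  n <- 200
  x <- c(rnorm(100, -3), rnorm(100, 3))
  y <- as.integer(x > 0)
  g <- factor(rep(1:2, 100))
  expect_warning(fit_mixed_logistic(cbind("(Intercept)" = 1, x = x), y, g, nAGQ = 1),
                 "quasi-separation")
})

test_that("GVIF matches the closed form and car's implementation", {
  set.seed(45)
  n <- 600
  z1 <- rnorm(n)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  X <- cbind("(Intercept)" = 1, a = z1, b = z2)
  cc <- check_collinearity(X, c("(Intercept)", "a", "b"))
  r <- cor(z1, z2)
  expect_equal(cc$gvif$gvif[cc$gvif$term == "a"], 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(1 / (1 - 0.9^2), 5.263, tolerance = 1e-3)
  # exactly orthogonal centred columns give GVIF 1
  q <- poly(seq_len(n), 3)
  Xo <- cbind("(Intercept)" = 1, u = q[, 1], v = q[, 2], w = q[, 3])
  co <- check_collinearity(Xo, colnames(Xo))
  expect_true(all(abs(co$gvif$gvif - 1) < 1e-8))
  # duplicated column is rank deficient
  Xd <- cbind(X, b2 = z2)
  expect_error(check_collinearity(Xd, c("(Intercept)", "a", "b", "b")),
               "rank-deficient")
  # cross-check multi-column GVIF against car::vif on a factor design
  if (requireNamespace("car", quietly = TRUE)) {
    df <- data.frame(y = rnorm(n), x = z1,
                     f = factor(sample(letters[1:3], n, TRUE)))
    m <- lm(y ~ x + f, df)
    ours <- check_collinearity(model.matrix(m),
                               c("(Intercept)", "x", "f", "f"))
    theirs <- car::vif(m)
    expect_equal(ours$gvif$gvif[ours$gvif$term == "x"],
                 unname(theirs["x", "GVIF"]), tolerance = 1e-6)
    expect_equal(ours$gvif$gvif[ours$gvif$term == "f"],
                 unname(theirs["f", "GVIF"]), tolerance = 1e-6)
  }
})

test_that("AIC selection applies the decisive Delta-AIC >= 10 rule", {
  mk <- function(aic, n = 100) structure(list(aic = aic, n_obs = n), class = "fit_result")
  sel <- aic_select(list(a = mk(112), b = mk(100)))
  expect_equal(sel$winner, "b")
  expect_true(sel$decisive)
  sel2 <- aic_select(list(a = mk(104), b = mk(100)))
  expect_equal(sel2$winner, "b")
  expect_false(sel2$decisive)
  expect_message(sel3 <- aic_select(list(a = mk(100), b = mk(100))), "tie")
  expect_false(sel3$decisive)
  expect_error(aic_select(list(a = mk(100), b = mk(90, n = 50))),
               "differing observation counts")
})

test_that("Nakagawa R2 matches its closed form", {
  fk <- structure(list(sigma2_f = 1, re_var = 1,
                       coefficients = data.frame(term = "x", estimate = 1)),
                  class = "fit_result")
  r2 <- r2_nakagawa(fk)
  expect_equal(unname(r2["marginal"]), 1 / (2 + pi^2 / 3), tolerance = 1e-6)
  expect_equal(unname(r2["marginal"]), 0.1890, tolerance = 1e-3)
  expect_equal(unname(r2["conditional"]), 0.3779, tolerance = 1e-3)
  fk0 <- structure(list(sigma2_f = 0.7, re_var = 0,
                        coefficients = data.frame(term = "x", estimate = 1)),
                   class = "fit_result")
  r20 <- r2_nakagawa(fk0)
  expect_equal(unname(r20["marginal"]), unname(r20["conditional"]))
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_lte(r2["marginal"], r2["conditional"])
})

test_that("scenario prediction inverts the logit at the population level", {
  set.seed(46)
  n <- 2000
  df <- data.frame(
    response = NA, animal_id = rep(c("a", "b"), each = n / 2),
    tod = factor(sample(c("day", "night", "twilight"), n, TRUE),
                 levels = c("day", "night", "twilight")),
    dist_raw = runif(n, 0, 3000)
  )
  prep <- prepare_model_data(df)
  prep$response <- rbinom(n, 1, plogis(-1 + 0.5 * prep$dist))
  fit <- fit_model(prep, c("dist", "tod"), nAGQ = 1)
  p0 <- predict_response(fit, list(dist = 0, tod = "day"))
  ic <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
  expect_equal(p0, plogis(ic), tolerance = 1e-10)
  expect_equal(plogis(-4.6966), 0.0090, tolerance = 1e-2)
  # monotonicity in a positive-coefficient covariate
  b_dist <- fit$coefficients$estimate[fit$coefficients$term == "dist"]
  p_hi <- predict_response(fit, list(dist = 1, tod = "day"))
  expect_true((p_hi > p0) == (b_dist > 0))
  expect_error(predict_response(fit, list(dist = 0)), "missing term")
})
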
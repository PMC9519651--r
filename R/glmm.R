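#' Build a fixed-effects design matrix from a labelled point table
#'
#' Terms are drawn from the model vocabulary: continuous columns (`cover`,
#' `ndvi`, `dist` and their quadratics `cover2`, `ndvi2`, `dist2`), the
#' factors `treatment` (reference "before") and `tod` (time of day,
#' reference "day"), the binary flags `calving` and `rut`, and `:`
#' interactions among them. Factors are dummy-coded against their reference
#' level; interaction columns are elementwise products; column order and
#' names are deterministic. Factor levels absent from the data are dropped
#' with a warning.
#'
#' @param points data.frame of labelled points (see [prepare_model_data()]).
#' @param terms character vector of term labels, e.g.
#'   `c("dist", "dist2", "treatment", "dist:treatment")`.
#' @param response name of the 0/1 response column.
#' @param group name of the grouping (animal id) column.
#' @return list with design matrix `X` (including the intercept column),
#'   response `y`, `groups` factor, `terms`, and `term_of_col` mapping each
#'   column to its term label.
#' @export
build_design <- function(points, terms, response = "response", group = "animal_id") {
  df <- as.data.frame(points)
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(base_vars, names(df))
  if (length(missing_vars)) {
    stop("unknown term variable(s): ", paste(missing_vars, collapse = ", "))
  }
  for (v in base_vars) {
    if (is.factor(df[[v]])) {
      present <- unique(as.character(df[[v]]))
      absent <- setdiff(levels(df[[v]]), present)
      if (length(absent)) {
        warning(sprintf("factor '%s': level(s) %s absent from data; columns dropped",
                        v, paste(absent, collapse = ", ")))
        df[[v]] <- factor(as.character(df[[v]]),
                          levels = intersect(levels(df[[v]]), present))
      }
    }
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  }
  ok <- stats::complete.cases(df[, base_vars, drop = FALSE])
  if (!all(ok)) {
    warning(sprintf("dropping %d row(s) with missing model variables", sum(!ok)))
    df <- df[ok, , drop = FALSE]
  }
  f <- stats::reformulate(terms)
  mm <- stats::model.matrix(f, df)
  tl <- attr(stats::terms(f), "term.labels")
  term_of_col <- c("(Intercept)", tl)[attr(mm, "assign") + 1L]
  # drop constant non-intercept columns (e.g. a flag that never varies)
  keep <- c(TRUE, apply(mm[, -1L, drop = FALSE], 2L, function(x) length(unique(x)) > 1L))
  if (!all(keep)) {
    warning("dropping constant design column(s): ",
            paste(colnames(mm)[!keep], collapse = ", "))
  }
  y <- df[[response]]
  if (is.null(y)) stop(sprintf("response column '%s' not found", response))
  list(X = mm[, keep, drop = FALSE],
       y = as.numeric(y),
       groups = factor(df[[group]]),
       terms = terms,
       term_of_col = term_of_col[keep])
}

#' Fit a random-intercept mixed logistic model
#'
#' Maximises the marginal likelihood of a logistic regression with one
#' Gaussian random intercept per group, with the per-group integral
#' approximated by adaptive Gauss-Hermite quadrature (default 9 nodes),
#' via `lme4::glmer`. Wald p-values come from the estimated covariance of
#' the fixed effects. Any fixed effect exceeding 15 on the link scale is
#' flagged as possible quasi-separation (the fit is returned with a
#' warning, not an error).
#'
#' @param X design matrix including an intercept column.
#' @param y 0/1 response vector.
#' @param groups grouping factor (>= 2 levels).
#' @param nAGQ number of adaptive quadrature nodes (>= 1; 1 = Laplace).
#' @return An object of class `fit_result`: coefficient table (estimate,
#'   SE, Wald z and p), random-intercept SD/variance, logLik, AIC,
#'   convergence info, and the variance of the fixed-effect linear
#'   predictor (used by the Nakagawa R-squared).
#' @export
fit_mixed_logistic <- function(X, y, groups, nAGQ = 9) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups for a random intercept")
  if (length(unique(y)) < 2L) stop("constant response")
  p <- ncol(X)
  dat <- as.data.frame(X)
  safe <- paste0(".x", seq_len(p))
  names(dat) <- safe
  dat$.y <- y
  dat$.g <- groups
  f <- stats::as.formula(paste(".y ~ 0 +", paste(safe, collapse = " + "), "+ (1 | .g)"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(f, data = dat, family = stats::binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(est) <- names(se) <- colnames(X)
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  re_var <- as.numeric(lme4::VarCorr(fit)$.g[1L])
  ll <- as.numeric(stats::logLik(fit))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  if (any(abs(est) > 15)) {
    warning("possible quasi-separation: |estimate| > 15 on the link scale")
  }
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(est),
                              se = unname(se), z = unname(z), p = unname(pval),
                              stringsAsFactors = FALSE),
    re_sd = sqrt(re_var),
    re_var = re_var,
    logLik = ll,
    aic = -2 * ll + 2 * (p + 1),
    n_obs = length(y),
    n_groups = nlevels(groups),
    nAGQ = nAGQ,
    converged = conv,
    messages = msgs,
    sigma2_f = stats::var(as.numeric(X %*% est))
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, groups = %d, nAGQ = %d%s\n",
              x$n_obs, x$n_groups, x$nAGQ,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, random-intercept SD = %.4f\n",
              x$logLik, x$aic, x$re_sd))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit a model from a labelled point table (design + mixed fit)
#'
#' Convenience wrapper: builds the design per [build_design()], fits via
#' [fit_mixed_logistic()], and stores the term list, factor levels and the
#' covariate scaling of the data so that predictions and RSF scoring can
#' reproduce the design exactly.
#'
#' @inheritParams build_design
#' @inheritParams fit_mixed_logistic
#' @return a `fit_result` with `terms`, `xlevels` and `scaling` attached.
#' @export
fit_model <- function(points, terms, response = "response", group = "animal_id",
                      nAGQ = 9) {
  d <- build_design(points, terms, response = response, group = group)
  fit <- fit_mixed_logistic(d$X, d$y, d$groups, nAGQ = nAGQ)
  fit$terms <- terms
  fit$term_of_col <- d$term_of_col
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  fit$xlevels <- lapply(
    stats::setNames(base_vars, base_vars),
    function(v) if (is.factor(points[[v]])) levels(droplevels(points[[v]])) else NULL
  )
  fit$xlevels <- Filter(Negate(is.null), fit$xlevels)
  fit$scaling <- attr(points, "scaling")
  fit
}

#' Collinearity screen: pairwise correlations and GVIF
#'
#' Pearson correlations among the continuous design columns, and the
#' generalised variance inflation factor per model term from the
#' determinant-ratio formulation
#' `GVIF = det(R[S,S]) det(R[-S,-S]) / det(R)` on the correlation matrix of
#' all non-intercept columns, with `GVIF^(1/(2 df))` reported alongside.
#'
#' @param X design matrix including the intercept column.
#' @param term_of_col character vector mapping columns to term labels
#'   (as returned by [build_design()]).
#' @return list with `correlations` (matrix, continuous columns only) and
#'   `gvif` (data.frame: term, df, gvif, gvif_adj).
#' @export
check_collinearity <- function(X, term_of_col) {
  ic <- which(term_of_col == "(Intercept)")
  Xc <- if (length(ic)) X[, -ic, drop = FALSE] else X
  toc <- if (length(ic)) term_of_col[-ic] else term_of_col
  R <- stats::cor(Xc)
  if (!is.finite(det(R)) || abs(det(R)) < 1e-12 || qr(Xc)$rank < ncol(Xc)) {
    stop("rank-deficient design (duplicated or aliased columns)")
  }
  is_cont <- apply(Xc, 2L, function(x) length(unique(x)) > 2L)
  correlations <- if (any(is_cont)) stats::cor(Xc[, is_cont, drop = FALSE]) else NULL
  terms <- unique(toc)
  gvif <- vapply(terms, function(t) {
    s <- which(toc == t)
    if (length(s) == ncol(Xc)) return(1)
    det(R[s, s, drop = FALSE]) * det(R[-s, -s, drop = FALSE]) / det(R)
  }, numeric(1))
  dfs <- vapply(terms, function(t) sum(toc == t), numeric(1))
  list(correlations = correlations,
       gvif = data.frame(term = terms, df = dfs, gvif = unname(gvif),
                         gvif_adj = unname(gvif^(1 / (2 * dfs))),
                         stringsAsFactors = FALSE, row.names = NULL))
}

#' AIC model selection with a decisive-difference rule
#'
#' The winner is the candidate with the lowest AIC; the choice is flagged
#' decisive only when the runner-up trails by at least `delta` AIC units
#' (default 10, a deliberately conservative cut).
#'
#' @param candidates named list of `fit_result`s fitted on identical data.
#' @param delta decisive Delta-AIC threshold.
#' @return list with `winner` (name), `table` (name, AIC, dAIC), and
#'   `decisive` (logical).
#' @export
aic_select <- function(candidates, delta = 10) {
  if (length(candidates) < 2L) stop("need >= 2 candidate fits")
  ns <- vapply(candidates, `[[`, numeric(1), "n_obs")
  if (length(unique(ns)) != 1L) stop("candidates fitted on differing observation counts")
  if (is.null(names(candidates))) names(candidates) <- paste0("m", seq_along(candidates))
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  ord <- order(aics)
  tab <- data.frame(model = names(candidates)[ord], aic = aics[ord],
                    daic = aics[ord] - min(aics), row.names = NULL,
                    stringsAsFactors = FALSE)
  decisive <- (tab$daic[2L] >= delta)
  if (tab$daic[2L] == 0) message("AIC tie between top candidates")
  list(winner = tab$model[1L], table = tab, decisive = decisive)
}

#' Nakagawa R-squared for a logistic GLMM
#'
#' Marginal R2 = s2_f / (s2_f + s2_re + pi^2/3) and conditional
#' R2 = (s2_f + s2_re) / (same denominator), where s2_f is the variance of
#' the fixed-effect linear predictor and pi^2/3 is the logistic
#' distribution-specific variance.
#'
#' @param fit a `fit_result`.
#' @param X optional design matrix to recompute s2_f; defaults to the value
#'   stored at fit time.
#' @return named numeric vector `c(marginal=, conditional=)`.
#' @export
r2_nakagawa <- function(fit, X = NULL) {
  s2f <- if (is.null(X)) fit$sigma2_f else {
    stats::var(as.numeric(X %*% fit$coefficients$estimate))
  }
  den <- s2f + fit$re_var + pi^2 / 3
  c(marginal = s2f / den, conditional = (s2f + fit$re_var) / den)
}

#' Population-level predicted probability for a covariate scenario
#'
#' Inverse-logit of the fixed-effect linear predictor (random intercept at
#' zero) at the given covariate/level settings.
#'
#' @param fit a `fit_result` from [fit_model()].
#' @param scenario named list supplying a value for every base variable of
#'   the model (scaled continuous values, factor levels as strings, logical
#'   flags). Quadratic columns are filled automatically.
#' @return predicted probability.
#' @export
predict_response <- function(fit, scenario) {
  if (is.null(fit$terms)) stop("fit lacks term metadata; use fit_model()")
  row <- .scenario_row(fit, scenario)
  x <- .design_row(row, fit)
  inv_logit(sum(x * fit$coefficients$estimate[match(names(x), fit$coefficients$term)]))
}

# build a one-row data.frame for a scenario, filling quadratics
.scenario_row <- function(fit, scenario) {
  base_vars <- unique(unlist(strsplit(fit$terms, ":", fixed = TRUE)))
  need <- setdiff(base_vars, c("cover2", "ndvi2", "dist2"))
  miss <- setdiff(need, names(scenario))
  if (length(miss)) stop("scenario missing term(s): ", paste(miss, collapse = ", "))
  row <- as.data.frame(scenario[intersect(names(scenario), need)],
                       stringsAsFactors = FALSE)
  for (v in c("cover", "ndvi", "dist")) {
    if (paste0(v, "2") %in% base_vars) row[[paste0(v, "2")]] <- row[[v]]^2
  }
  for (v in names(fit$xlevels)) {
    row[[v]] <- factor(as.character(row[[v]]), levels = fit$xlevels[[v]])
    if (any(is.na(row[[v]]))) stop(sprintf("scenario level for '%s' not in model", v))
  }
  row
}

# evaluate the design row for one scenario against the fit's coefficient terms
.design_row <- function(row, fit) {
  for (v in names(row)) if (is.logical(row[[v]])) row[[v]] <- as.numeric(row[[v]])
  mm <- stats::model.matrix(stats::reformulate(fit$terms), row,
                            xlev = fit$xlevels)
  x <- mm[1L, ]
  x[names(x) %in% fit$coefficients$term]
}
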
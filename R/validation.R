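#' k-fold and animal-blocked cross-validation of an RSF
#'
#' For each fold the RSF model is refitted on the training data, held-out
#' used and available points are scored, scores are binned into quantile
#' bins of the held-out available-score distribution (equal availability
#' mass per bin), the area-adjusted frequency per bin is computed as
#' (share of used in bin) / (share of available in bin), and the Spearman
#' rank correlation between bin rank and adjusted frequency is reported
#' (ranks averaged on ties). A well-predicting RSF concentrates used points
#' in high-score bins, giving rho near 1.
#'
#' Fold construction: random folds are stratified by animal so every
#' training set contains every animal; blocked folds assign whole animals
#' round-robin by data volume (largest first onto the currently smallest
#' fold), testing transferability across individuals.
#'
#' @param data prepared modelling table (scaled covariates present) with
#'   `response` and `animal_id`.
#' @param terms model terms; required unless `score_fun` is given.
#' @param k number of folds (>= 2; `by_animal` needs >= k animals).
#' @param blocking "random" or "by_animal".
#' @param n_bins number of quantile bins.
#' @param seed integer seed for fold assignment.
#' @param score_fun optional function(data.frame) -> scores; when supplied
#'   no refitting happens (e.g. scoring by a known generating model, or by
#'   random scores as a null reference).
#' @param alpha retention cut passed to [build_rsf()] for per-fold refits;
#'   if a fold has no significant term, all terms are retained with a
#'   warning.
#' @param nAGQ quadrature nodes for per-fold refits.
#' @return list with `folds` (data.frame: fold, blocking, n_test, rho) and
#'   `mean_rho`.
#' @export
kfold_cv <- function(data, terms = NULL, k = 5, blocking = c("random", "by_animal"),
                     n_bins = 10, seed = 1L, score_fun = NULL, alpha = 0.05,
                     nAGQ = 1) {
  blocking <- match.arg(blocking)
  if (k < 2) stop("k must be >= 2")
  if (is.null(score_fun) && is.null(terms)) stop("need terms or score_fun")
  animals <- as.character(data$animal_id)
  fold <- integer(nrow(data))
  if (blocking == "random") {
    with_seed(seed, {
      for (a in unique(animals)) {
        idx <- which(animals == a)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
  } else {
    tab <- sort(table(animals), decreasing = TRUE)
    if (length(tab) < k) stop("by_animal blocking needs >= k animals")
    load <- numeric(k)
    for (a in names(tab)) {
      f <- which.min(load)
      fold[animals == a] <- f
      load[f] <- load[f] + tab[[a]]
    }
  }
  rhos <- numeric(k)
  n_test <- integer(k)
  for (f in seq_len(k)) {
    test <- data[fold == f, , drop = FALSE]
    if (sum(test$response == 1) == 0L) stop(sprintf("fold %d has no used points", f))
    scores <- if (is.null(score_fun)) {
      train <- data[fold != f, , drop = FALSE]
      fit <- fit_model(train, terms, nAGQ = nAGQ)
      rsf <- tryCatch(build_rsf(fit, alpha = alpha), error = function(e) {
        warning(sprintf("fold %d: no significant terms; retaining all", f))
        build_rsf(fit, alpha = 1)
      })
      .score_prepared(rsf, test)
    } else {
      score_fun(test)
    }
    rhos[f] <- cv_rho(scores, test$response, n_bins = n_bins)
    n_test[f] <- nrow(test)
  }
  list(folds = data.frame(fold = seq_len(k), blocking = blocking,
                          n_test = n_test, rho = rhos),
       mean_rho = mean(rhos))
}

# score a prepared table (scaled columns already present) against an RSF's
# retained coefficients, bypassing re-scaling
.score_prepared <- function(rsf, data) {
  df <- data
  for (v in c("cover", "ndvi", "dist")) {
    df[[paste0(v, "_raw")]] <- NULL  # force use of prepared scaled columns
  }
  lp <- rep(0, nrow(df))
  cellvals <- df[, intersect(c("cover", "cover2", "ndvi", "ndvi2", "dist", "dist2"),
                             names(df)), drop = FALSE]
  treatment <- as.character(df$treatment %||% rep("before", nrow(df)))
  tod <- as.character(df$tod %||% rep("day", nrow(df)))
  calving <- as.logical(df$calving %||% rep(FALSE, nrow(df)))
  rut <- as.logical(df$rut %||% rep(FALSE, nrow(df)))
  for (nm in names(rsf$coefficients)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    val <- rep(1, nrow(df))
    for (p in parts) {
      val <- val * if (p %in% names(cellvals)) {
        cellvals[[p]]
      } else if (grepl("^treatment", p)) {
        as.numeric(paste0("treatment", treatment) == p)
      } else if (grepl("^tod", p)) {
        as.numeric(paste0("tod", tod) == p)
      } else if (p %in% c("calving", "calvingTRUE")) {
        as.numeric(calving)
      } else if (p %in% c("rut", "rutTRUE")) {
        as.numeric(rut)
      } else {
        stop("cannot score term part: ", p)
      }
    }
    lp <- lp + rsf$coefficients[[nm]] * val
  }
  exp(lp)
}

#' Binned area-adjusted Spearman rho of RSF scores
#'
#' The validation statistic used per fold: scores are cut into `n_bins`
#' quantile bins of the available-score distribution, the area-adjusted
#' used frequency per bin is (used share)/(available share), and rho is the
#' Spearman correlation of adjusted frequency with bin rank.
#'
#' @param scores numeric scores for all held-out points.
#' @param response 0/1 vector (1 = used).
#' @param n_bins number of quantile bins.
#' @return Spearman rho.
#' @export
cv_rho <- function(scores, response, n_bins = 10) {
  avail <- scores[response == 0]
  used <- scores[response == 1]
  if (length(avail) == 0L || length(used) == 0L) stop("need used and available scores")
  qs <- stats::quantile(avail, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7)
  qs <- unique(qs)
  if (length(qs) < 3L) stop("degenerate score distribution: too few distinct bins")
  edges <- qs[-c(1L, length(qs))]
  bin_of <- function(x) findInterval(x, edges) + 1L
  nb <- length(edges) + 1L
  ua <- tabulate(bin_of(used), nbins = nb) / length(used)
  aa <- tabulate(bin_of(avail), nbins = nb) / length(avail)
  keep <- aa > 0
  adj <- ua[keep] / aa[keep]
  stats::cor(seq_len(sum(keep)), adj, method = "spearman")
}

#' Compare fitted coefficients to the generating truth
#'
#' Per-term truth, estimate, difference and `|z| = |estimate - truth| / SE`
#' over the vocabulary shared by the true model and the fit, plus sign
#' agreement. The harness behind the parameter-recovery property.
#'
#' @param truth a `true_model`.
#' @param fit a `fit_result`.
#' @return data.frame (term, truth, estimate, se, diff, z, sign_agree).
#' @export
recovery_report <- function(truth, fit) {
  cf <- fit$coefficients
  shared <- intersect(names(truth$coefficients), cf$term)
  if (length(shared) == 0L) stop("true model and fit share no terms")
  tr <- truth$coefficients[shared]
  est <- cf$estimate[match(shared, cf$term)]
  se <- cf$se[match(shared, cf$term)]
  data.frame(term = shared, truth = unname(tr), estimate = est, se = se,
             diff = est - unname(tr), z = (est - unname(tr)) / se,
             sign_agree = sign(est) == sign(unname(tr)),
             row.names = NULL, stringsAsFactors = FALSE)
}
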
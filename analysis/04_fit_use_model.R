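#!/usr/bin/env Rscript
# Stage 4: seasonal site-use models.
#
# Mixed logistic regression of presence inside a grazing site (1/0 per used
# fix) on time of day, treatment and their interaction, with an animal
# random intercept; summer candidates with and without the rut and calving
# flags are compared by AIC (a Delta-AIC >= 10 makes the choice decisive).
# Collinearity is screened by pairwise correlation and GVIF; Nakagawa
# marginal/conditional R2 summarise explained variance.

library(grazeRSF)

s1 <- readRDS("scratch/analysis/stage1.rds")
s3 <- readRDS("scratch/analysis/stage3.rds")

used <- s3$used
used$response <- point_in_sites(used[, c("x", "y")], s1$study$sites)

for (season in c("summer", "winter")) {
  su <- droplevels(used[used$season == season, ])
  if (length(unique(su$response)) < 2L || length(unique(su$animal_id)) < 2L) {
    message(sprintf("%s: insufficient data for a use model", season))
    next
  }
  su <- prepare_model_data(su)
  base_terms <- c("tod", "treatment", "tod:treatment")
  candidates <- list(base = base_terms)
  if (season == "summer") {
    candidates$with_rut <- c(base_terms, "rut")
    candidates$with_calving <- c(base_terms, "calving")
    candidates$with_both <- c(base_terms, "rut", "calving")
  }
  fits <- suppressWarnings(lapply(candidates, function(tt) fit_model(su, tt, nAGQ = 9)))
  if (length(fits) > 1L) {
    sel <- aic_select(fits)
    message(sprintf("%s use model: winner '%s' (decisive: %s)",
                    season, sel$winner, sel$decisive))
    write.csv(sel$table, sprintf("results/04_use_model_aic_%s.csv", season),
              row.names = FALSE)
    fit <- fits[[sel$winner]]
  } else {
    fit <- fits[[1L]]
  }
  d <- suppressWarnings(build_design(su, fit$terms))
  coll <- check_collinearity(d$X, d$term_of_col)
  write.csv(coll$gvif, sprintf("results/04_use_model_gvif_%s.csv", season),
            row.names = FALSE)
  r2 <- r2_nakagawa(fit, d$X)
  message(sprintf("%s: n=%d, R2 marginal %.3f / conditional %.3f, RE sd %.2f",
                  season, fit$n_obs, r2["marginal"], r2["conditional"], fit$re_sd))
  write_fit(fit, sprintf("results/04_use_model_%s.csv", season),
            sprintf("results/04_use_model_%s.json", season))
  # predicted probability of site use by treatment and time of day
  scen <- expand.grid(treatment = fit$xlevels$treatment, tod = fit$xlevels$tod,
                      stringsAsFactors = FALSE)
  scen$probability <- vapply(seq_len(nrow(scen)), function(i) {
    predict_response(fit, c(list(treatment = scen$treatment[i], tod = scen$tod[i]),
                            if ("rut" %in% fit$terms) list(rut = FALSE),
                            if ("calving" %in% fit$terms) list(calving = FALSE)))
  }, numeric(1))
  write.csv(scen, sprintf("results/04_use_probability_%s.csv", season),
            row.names = FALSE)
}
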
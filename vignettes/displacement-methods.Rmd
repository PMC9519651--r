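---
title: "Modelling displacement of red deer by herded conservation grazing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling displacement of red deer by herded conservation grazing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the two-step design

Conservation grazing — herded sheep and goat flocks maintaining open
heathland — introduces a mobile, dog-accompanied disturbance into areas
that wild red deer (*Cervus elaphus*) use as foraging grounds. The package
implements a two-step analysis of GPS telemetry around such grazing sites:

1. **Site-use model.** A random-intercept logistic GLMM of whether each fix
   falls inside a grazing site, as a function of time of day, a 21-day
   treatment category relative to the grazing term, and calving/rut flags.
2. **Resource selection functions (RSFs).** A use–availability design: each
   used fix is contrasted with 16 random locations from the animal's
   0.99 kernel home range; the mixed logistic fit's significant
   coefficients (p < 0.05) define `w(x) = exp(Σ βx)`, a relative selection
   score evaluated along distance gradients and over raster maps.

Because the original telemetry is not public, the package is exercised
end-to-end on synthetic telemetry drawn from a known true selection model,
so every stage can be checked against ground truth.

## Temporal context

**Treatment windows.** Each grazing term of a site group defines four
21-day categories: *before* (`[start − 21 d, start)`), *early* (days 1–21),
*ongoing* (days 22–42) and *after* (the 21 days following the term's end).
Two boundary rules are the package's own decisions, recorded here:

* Days 43+ of a long term are left unassigned — the analysis uses exactly
  four 21-day categories, and later grazing days belong to none of them.
* A term shorter than 42 days yields **no** ongoing category at all (its
  days 22+ are unassigned). A 25-day December term therefore produces only
  three treatment levels, matching the seasonal-model structure the design
  calls for. The alternative — a 4-day "ongoing" sliver — would create a
  category estimated from a handful of fixes.

Windows are defined on local calendar dates (a configurable fixed UTC
offset, default +1 h), because "21 days" is calendar language, not a
rolling 24-h clock. If windows of consecutive terms ever overlap, labels
tied to an active term (early/ongoing) take precedence over after, and
after over before.

**Solar classes.** Day is `[sunrise, sunset)`; twilight is
`[nautical dawn, sunrise) ∪ [sunset, nautical dusk)`; night is the rest, so
the three classes partition every day, and a timestamp exactly on an event
falls into the later class. Events come from the standard NOAA solar
formulas (elevation −0.833° for rise/set, −12° for the nautical events),
evaluated at a single study-area reference coordinate — the study area
spans well under 0.2°, so per-fix solar geometry would change nothing.
Against an independent ephemeris implementation the solstice sunrise agrees
to under a minute.

**Filters and flags.** Fixes failing the quality screen (the ≥4-satellite
flag) are dropped before any labelling. Fixes on a driven-hunt day or any
of the six following days are excluded; overlapping hunt windows are
unioned. Calving is 15 May–15 June (females only); rut is
1 September–15 October; summer is May–October, winter November–January,
February–April is excluded from the seasonal models.

## Home ranges and availability

The utilization distribution is a bivariate Gaussian fixed-kernel density
on a metric grid (default cell 20 m, padded ≥3 bandwidths beyond the data).
The "reference" bandwidth is the Silverman/Worton plug-in
`h = sqrt((s²x + s²y)/2) · n^(−1/6)`. The 0.99 isopleth is found by sorting
cells by density and accumulating mass until 99% is reached; all cells
tying with the threshold density are included, and the cell set is
polygonised along the threshold contour. Home ranges always use **all** of
an animal's fixes, independent of treatment filtering.

Availability points are drawn uniformly from the isopleth region by
sampling a member cell uniformly and jittering within it. This replaces
bounding-box rejection sampling: the region *is* a cell set, so cell
sampling is exactly uniform and never rejects. Each available point
inherits the timestamp — hence every temporal label — of its paired used
point, and carries response 0.

The 1:16 ratio is treated as the study condition; `ratio_sensitivity()`
reproduces the supporting analysis by refitting at increasing ratios and
reporting the consecutive relative coefficient change
`|Δβ|/max(|β|, SE)`, selecting the smallest ratio from which all subsequent
changes stay below 5%. The 5% figure and the SE floor are package choices;
the floor prevents near-zero coefficients from blocking stabilisation.

## The mixed logistic engine

Both models are random-intercept logistic GLMMs fitted by maximising the
marginal likelihood with adaptive Gauss–Hermite quadrature (≥9 nodes;
`lme4::glmer` does the optimisation). The test suite pins this contract to
an independent brute-force oracle — fine fixed-grid quadrature over the
random effect plus an iterated parameter grid search — which the fitted
marginal log-likelihood matches to 10⁻⁴ on a small fixture, and to a plain
IRLS logistic fit when the variance estimate is zero.

Reference levels are *day* and *before*; factors are dummy-coded and
interaction columns are elementwise products, so coefficient names like
`dist:treatmentongoing` are stable identifiers across the whole package.
p-values are Wald (matching coefficient-table practice), AIC is
`−2 logLik + 2(p + 1)`, and model choice is by lowest AIC, flagged decisive
only when the runner-up trails by ≥10. Any |coefficient| > 15 on the link
scale triggers a quasi-separation warning but not an error — rare
category × period combinations can be legitimately empty, and the model is
still reported. Collinearity is screened by pairwise Pearson correlations
and the determinant-ratio GVIF with `GVIF^(1/(2 df))`. Nakagawa R² uses the
logistic distribution-specific variance π²/3.

Continuous covariates are z-standardised once per seasonal dataset (used
and available pooled) and the parameters stored; quadratics are squares of
the *scaled* variable. Map prediction and scenario scoring always reuse the
stored parameters — never rescale on new data.

## The RSF and its scenarios

`build_rsf()` retains exactly the coefficients with p below the cut
(intercept always excluded). Retention is per coefficient, not per term: a
significant interaction stays even when a parent main effect drops, because
the selection rule is "significant coefficients", applied literally; an
optional flag enforces hierarchy instead. Scores are strictly positive, and
score–distance profiles are scaled by the scenario-specific median so
scenarios share a reference level. Maps fix one scenario (treatment, time
of day, flags) per map and measure distance from cell centres, zero inside
sites. Rasters are exchanged as ESRI ASCII grids — a plain-text format any
GIS reads.

## Validation

Cross-validation refits the same model specification per fold (no
re-selection inside folds), scores held-out used and available points, cuts
scores into ten quantile bins of the held-out *available* score
distribution (equal availability mass per bin; the bin count is a package
choice), computes the area-adjusted frequency (used share / available
share) per bin, and reports the Spearman correlation of adjusted frequency
with bin rank. Random folds are stratified by animal so every training set
contains every animal; blocked folds assign whole animals, largest first,
onto the currently smallest fold — the blocked variant tests whether
selection transfers to unseen individuals.

## The synthetic study system

`reference_study()` builds the fixed synthetic setting: a 7 km square
landscape at 20 m resolution with tree-cover and NDVI fields (Gaussian-
smoothed white noise, 300 m correlation length, min–max rescaled into
0–100% and −0.2–0.9), three grazing sites of ~62, 22 and 102 ha in a
northern and a southern group, a 25-day December term in the first year and
June–September/October summer terms split across the groups thereafter, two
driven hunts per winter, and the reference coordinate 51.88° N, 12.98° E.

`simulate_deer()` draws each 2-hourly fix independently from the landscape
cells inside the animal's home polygon with weight `exp(linear predictor)`
under that fix's temporal context. This deliberately matches the RSF's
exchangeability assumption — there is no serial autocorrelation, no
movement mechanics, no forage phenology — so passing tests certify the
statistical pipeline, not realism of movement. Real telemetry violates
independence, which widens true confidence intervals relative to the
simulated setting.

Two structural facts about the paired design surface in the generator:

* **Animal intercepts cancel.** Each fix is a normalised draw over cells,
  so a per-animal intercept shifts nothing; in the paired use–availability
  fit the estimated random-intercept variance is correspondingly near zero.
  The intercept is still drawn (SD 0.5) because it is part of the stated
  generative model, and it matters for the binary site-use series, where
  it appears directly in the Bernoulli probability.
* **Treatment main effects are not selection parameters.** With one used
  point per timestamp and availability paired to it, a treatment main
  effect is constant within each stratum and absorbs the log normalising
  constant of that context. The generating truth therefore carries no
  treatment mains; the fitted model includes them (they keep the
  likelihood correctly specified) but recovery is judged on the shared
  vocabulary: distance, distance², and the distance × treatment
  interactions.

## The recovery study

The end-to-end check simulates ten animals × 9000 fixes (capped at 2000
used fixes per animal inside treatment windows, then paired 1:16 — roughly
340,000 rows in the final fit) from a truth with `dist = −0.6`,
`dist² = −0.35` and distance × treatment interactions of +0.35/+0.6/+0.45
(early/ongoing/after), all magnitudes within 0.3–0.8, on the reference
scaling (distance: mean 1500 m, SD 900 m). The pipeline must recover every
shared coefficient within ±3 reported SEs with full sign agreement, and the
fitted score–distance profiles must move the daytime selection peak away
from the sites between the *before* and *ongoing* scenarios.

Two design choices make this estimand well-posed:

* **Home polygons are generous rectangles** around each group's sites, so
  the covariate model — not a tight boundary — shapes the utilization and
  the 0.99 isopleth lies inside true availability. With tight home
  polygons, kernel smoothing pushes the isopleth into area the generator
  could never use, and the availability contrast is then biased by
  construction.
* **The home-range bandwidth is fixed at 150 m** in this harness rather
  than the reference plug-in. The reference bandwidth (~300–400 m at these
  sample sizes and ranges) is known to oversmooth boundary-constrained
  telemetry; the inflated isopleth again injects never-used area into
  availability. 150 m is of the order of the distance between consecutive
  2-hourly fixes and keeps the isopleth aligned with the region the
  animal's distribution actually occupies. The pipeline default elsewhere
  remains the reference bandwidth, and it is recorded in every output.

Fitted coefficients are compared on the truth's reference scaling (the
harness passes it into covariate preparation); the default pipeline path
computes scaling from the data, which would put estimates on a different,
data-dependent scale.

## Problem sizes and runtime

The bundled analysis scripts and tests run at the sizes above: the full
recovery fit takes a few minutes on one core; cross-validation inside the
analysis scripts uses a 1:4 availability re-draw and the Laplace
approximation for per-fold refits, which changes fold rho by far less than
its fold-to-fold spread. The acceptance script repeats the recovery run,
the CV study (~12,500 points), 50 AIC model-selection replicates
(~1,800 observations each) and the closed-form spot checks.

## Known limitations

* No movement model: step lengths, turning angles and serial dependence
  are out of scope; estimates on real telemetry should use robust or
  autocorrelation-aware inference.
* One scalar random intercept; no random slopes or crossed effects.
* Rasters must share one planar metric grid; no reprojection.
* The solar implementation targets mid-latitudes; above the polar circles
  events can be absent and the day/twilight split degenerates.
* The December-term rule (no ongoing category for short terms) and the
  43+-day rule are analysis conventions; with real schedules the sensitivity
  of conclusions to these windows deserves a check of its own.
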
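# grazeRSF

Does herded conservation grazing — a shepherded sheep and goat flock
maintaining open heathland — displace wild red deer from the grazing sites
and their surroundings? `grazeRSF` implements the full statistical pipeline
for answering that question from GPS telemetry, and exercises it end-to-end
on synthetic telemetry with known ground truth.

The analysis has two steps:

1. **Site-use model** — a random-intercept logistic GLMM of whether each
   2-hourly GPS fix falls inside a grazing site, with time of day (day /
   night / twilight from solar geometry), a 21-day treatment category
   relative to each grazing term (*before*, *early*, *ongoing*, *after*),
   and calving/rut flags as predictors, and animal identity as the random
   effect.
2. **Seasonal resource selection functions (RSFs)** — a use–availability
   design: every used fix is contrasted with 16 random locations from the
   animal's 0.99 fixed-kernel home range (paired timestamps), and the
   mixed logistic fit's significant coefficients (p < 0.05) define the
   exponential selection score

   w(x) = exp(β₁x₁ + β₂x₂ + … + βₙxₙ),

   evaluated along distance-to-site gradients and over raster maps, and
   validated by five-fold and animal-blocked cross-validation using binned,
   area-adjusted frequency correlation (Spearman ρ).

Around these sit the supporting stages wildlife telemetry work needs:
driven-hunt exclusion windows, season splits, minimum convex polygons,
kernel density home ranges and isopleths, raster covariates (tree cover,
NDVI), covariate scaling, GVIF collinearity screening, ΔAIC ≥ 10 model
selection, Nakagawa R², and a synthetic-data module (landscapes, grazing
schedules, telemetry from a true selection model) that gives every
downstream stage a known truth to recover.

## Worked example

The `analysis/` scripts run the whole study in order
(`Rscript analysis/01_simulate_study.R`, then `02_…` through `07_…`),
writing tables under `results/`. Stage 1 simulates ten collared deer
(2-hourly fixes, ~2 years) on a 7 km synthetic heath landscape with three
grazing sites (~62/22/102 ha) from the true model

```
                 dist                 dist2   dist:treatmentearly
                -0.60                 -0.35                  0.35
dist:treatmentongoing   dist:treatmentafter
                 0.60                  0.45
```

i.e. deer are attracted to the sites at baseline and that attraction
weakens through the grazing treatments. The later stages printed, on this
run:

```
90000 fixes total; 4080 excluded around driven hunts; 23580 in treatment windows.
RSF dataset: 338334 rows (20000 used, ratio 1:16).
summer RSF: n=293453, AIC 130593.1
  recovery vs truth: max |z| = 2.02, sign agreement 5/5
winter RSF: n=44881, AIC 19961.7
  recovery vs truth: max |z| = 1.79, sign agreement 4/4
  season  blocking       rho
  summer by_animal 0.913
  winter by_animal 0.870
  summer    random 0.908
  winter    random 0.821
Summer RSF retains 9 significant coefficients.
  scenario peak_distance_m
     before             600
      early            1100
    ongoing            1450
      after            1250
Selection peak shifts 850 m away from the sites between 'before' and 'ongoing'.
```

Reading this: every true coefficient is recovered within 2 standard errors
with the right sign (the winter model has no *ongoing* level because the
25-day December term is too short to contain one); the fitted RSFs rank
held-out use well (mean ρ 0.82–0.91); and the fitted score–distance
profiles reproduce the displacement pattern — daytime selection peaks 600 m
from the sites before grazing, moves out to 1450 m while grazing is
ongoing, and only partly returns (1250 m) in the three weeks after.

A one-call version of the same machinery is available in R:

```r
library(grazeRSF)
rec <- recovery_run(seed = 1)   # simulate -> label -> home ranges ->
print(rec$report)               #   availability -> covariates -> GLMM
```

## Package layout

- `R/` — the implementation: synthetic data (`generate_landscape`,
  `generate_schedule`, `simulate_deer`, `simulate_use_series`), temporal
  context (`solar_events`, `classify_time_of_day`, `assign_treatment`,
  `exclude_hunt_windows`), home ranges (`kde_surface`, `isopleth_polygon`,
  `sample_available`, `ratio_sensitivity`, `mcp`), covariates, the GLMM
  layer (`build_design`, `fit_mixed_logistic`, `check_collinearity`,
  `aic_select`, `r2_nakagawa`), the RSF layer (`build_rsf`, `rsf_score`,
  `predict_map`, `score_distance_profile`), validation (`kfold_cv`,
  `recovery_report`) and the pipeline driver (`run_pipeline`).
- `analysis/` — numbered narrative drivers for the full study.
- `vignettes/displacement-methods.Rmd` — the model, its assumptions, and
  every recorded methodological decision.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.

Rasters are exchanged as ESRI ASCII grids, site polygons and isopleths as
GeoJSON, schedules/relocations/coefficient tables as CSV, and fit
diagnostics and manifests as JSON.
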
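# dietcalib

Survival analysis of diet–mortality associations when the exposure is an
error-prone food-frequency-questionnaire (FFQ) measure, for epidemiologists
and biostatisticians working with age-structured cohorts. The motivating
setting is a low-meat-intake cohort in which most subjects report **zero**
red or processed meat, so the contrast of interest is the 90th percentile
of intake versus zero intake.

The package covers the whole pipeline:

- **FFQ processing** — product-sum conversion of categorical
  frequency/serving responses to g/day, food-group aggregation,
  residual-method energy adjustment, cohort exclusion filters with an
  auditable ledger, and zero + consumer-quartile categorisation.
- **Survival engine** — its own left-truncated Cox
  partial-likelihood engine on the attained-age time scale (Efron/Breslow
  ties, Newton–Raphson, Rcpp risk-set sweep), with hazard-ratio contrasts,
  quartile-median trend tests, 4-knot restricted cubic splines,
  Schoenfeld/age-interaction proportional-hazards diagnostics, and
  interaction tests. ICD-10 cause codes are classified as CVD (I00–I78),
  cancer (C00–C97) or unnatural (U/V/W/X/Y prefixes, censored at death).
- **Measurement-error correction** — regression calibration against
  replicate 24-h recalls, bias-corrected and accelerated (BCa) bootstrap
  intervals for the calibrated hazard ratios, and deattenuated validity
  correlations from recall variance components.
- **Missing data** — chained-equations multiple imputation (PMM +
  multinomial draws) and Rubin's-rules pooling.
- **Orchestration** — `run_full_analysis()` executes the full
  exposure × outcome × model-tier grid with subgroup, never-smoker and
  population-attributable-risk analyses.
- **Synthetic cohorts** — `simulate_cohort()` generates zero-inflated,
  copula-correlated intakes with classical FFQ error, a recall substudy,
  left-truncated Weibull survival with ICD-10-like causes, and MAR
  covariate missingness, together with the ground truth used by the test
  battery.

## The model in brief

Hazard on the age scale: `h_i(t) = h0(t) exp(beta * g(x_i) + gamma' z_i)`
with risk sets `{i : entry_i < t <= exit_i}` (left truncation) and
`g(x) = log(1 + x)` so that zero intake is a valid reference. Reported
contrast: `HR = exp(beta * (g(x90) - g(0)))`. Regression calibration fits
`E[recall | FFQ, z]` in a substudy by OLS and substitutes its predictions
for the FFQ exposure; under classical error with reliability `lambda` the
naive log-HR estimates `lambda * beta` while the two-stage estimator
recovers `beta`. Pooling across `m` imputations uses
`T = W + (1 + 1/m) B`; attributable risk uses Levin's formula
`p(HR-1)/(1 + p(HR-1))`.

## Worked example

```r
library(dietcalib)

sim  <- simulate_cohort(sim_config(n_subjects = 6000, seed = 5,
                                   substudy_size = 400))
spec <- analysis_spec(exposures = "combined", outcomes = "all_cause",
                      m = 2, seed = 2)
report <- run_full_analysis(sim$cohort, sim$substudy, spec)
print(report)
```

```
Study report: n = 5960 ; events: ev_all_cause 662, ev_cvd 241, ev_cancer 152 
  combined:all_cause:model1    90th-vs-0 HR 1.55 (1.32-1.82); calibrated 1.60 (1.35-1.89) 
  combined:all_cause:model2    90th-vs-0 HR 1.51 (1.29-1.78); calibrated 1.55 (1.31-1.84) 
  combined:all_cause:model3    90th-vs-0 HR 1.52 (1.29-1.78); calibrated 1.56 (1.31-1.84) 
  PAR (all_cause): 5.3%
```

Reading the output: 40 of the 6000 simulated subjects fell to the
exclusion filters (extreme energy etc.), leaving n = 5960. Each row is one
model tier for the combined red + processed meat exposure and all-cause
mortality: the uncalibrated hazard ratio compares the 90th percentile of
energy-adjusted intake with zero intake on the log1p scale, the calibrated
version replaces the FFQ exposure by its regression-calibration prediction
from the 400-subject recall substudy, and both are Rubin-pooled over the
imputations. The generator's true contrast is HR 1.5, inside every
interval. The PAR line says 5.3% of deaths would be attributable to
intake at/above the 90th percentile if the association were causal.

The fitting functions are usable on their own — `cox_lt()` (left-truncated
Cox, with `summary`/`coef`/`vcov`/`confint`/`residuals` methods),
`rc_cox()` (two-stage calibrated contrast, optional BCa bootstrap),
`bootstrap_bca()`, `impute_cohort()` + `rubin_pool()`,
`deattenuate_correlation()` — see the help pages and the methods vignette
(`vignettes/diet-mortality-calibration.Rmd`).

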
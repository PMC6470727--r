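---
title: "Regression-calibrated survival analysis of dietary exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-calibrated survival analysis of dietary exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cohort studies of diet and mortality face three intertwined statistical
problems. First, the exposure — habitual intake of a food group in g/day —
is measured by a food frequency questionnaire (FFQ), an error-prone
instrument; classical measurement error attenuates hazard ratios toward the
null by roughly the exposure's reliability. Second, mortality follow-up is
age-structured: subjects enrol at widely different ages, so the natural Cox
time scale is attained age with left truncation at the age of entry. Third,
covariates collected by questionnaire have sporadic missingness.

`dietcalib` implements the full pipeline for this setting: FFQ response
processing, residual-method energy adjustment, a left-truncated Cox engine,
regression calibration of the exposure against replicate 24-h dietary
recalls with BCa bootstrap intervals, multiple imputation with Rubin's
rules, trend/spline/interaction/proportional-hazards inference, population
attributable risk, and a synthetic-cohort generator with known ground truth
for validating every step. The emulated setting is a large North-American
cohort with *low* meat intake — most subjects report zero red or processed
meat — so the exposure contrast of interest is the 90th percentile of
intake versus zero intake.

# The core model

For subject $i$ with entry age $a_i$, exit age $t_i$ and covariates $z_i$,
the hazard on the age scale is

$$h_i(t) = h_0(t)\, \exp\{\beta\, g(x_i) + \gamma' z_i\},$$

with $g(x) = \log(1+x)$ by default. The partial likelihood uses risk sets
$R(t) = \{i : a_i < t \le t_i\}$ (left truncation), maximised by
Newton–Raphson with Efron's tie correction. The reported contrast is

$$\mathrm{HR}(x_1\!:\!x_0) = \exp\{\hat\beta\,(g(x_1) - g(x_0))\},$$

typically $x_1 =$ the 90th percentile of energy-adjusted intake and
$x_0 = 0$.

**Regression calibration.** In a substudy, subjects provide $k$ recall
replicates; the calibration model regresses the recall mean on the FFQ
value and the analytic covariates (OLS). Predicted values replace the FFQ
exposure in the Cox model. Under classical error with reliability
$\lambda$, the naive coefficient estimates $\lambda\beta$ and the
calibration slope estimates $\lambda$, so the two-stage estimator recovers
$\beta$ (exactly so in the linear-calibration, small-$\beta$ regime; the
package's tests verify this at reliability 0.5). Only exposures are
calibrated, never covariates, and the calibration model always controls for
exactly the covariates of the analytic model being calibrated.

**Why $g = \log(1+x)$.** The published analyses log-transform intake yet
contrast against zero intake, where $\log$ is undefined. We resolve this by
defaulting to $\log(1+x)$, which is log-like for realistic intakes and
satisfies $g(0)=0$ so the zero-intake reference is well defined; a plain
`log` and `identity` transform remain selectable, and every function takes
the transform explicitly so both conventions can be reported side by side.

# Energy adjustment

Dietary exposures are energy-adjusted by the residual method: OLS of intake
on total energy, keeping residual + mean, which preserves the mean and
makes the adjusted variable exactly orthogonal to energy (and idempotent
under re-adjustment). One consequence worth recording: in any model that
already includes total energy as a covariate, replacing the exposure by its
energy residual is a linear reparameterisation, so the exposure
*coefficient* is unchanged. Energy adjustment therefore matters where the
variable is used directly — quartile cut-points, the 90th-percentile
contrast value, and descriptive tables — and the pipeline uses the adjusted
variable exactly there, while continuous model fits carry energy as a
covariate. The zero-intake group is always defined by reported zero intake,
not by the (possibly negative) adjusted value.

# Categories, trend, splines, diagnostics

The five-level exposure is zero intake plus quartiles of consumers. The
quartile cut-points default to the consumer distribution
(`quartile_basis = "consumers"`): with two-thirds of the cohort at zero,
total-cohort quartiles collapse onto the zero mass. A `"total"` basis is
available for cohorts where that is the published convention. The trend
test assigns each subject the median intake of their category (the zero
level scores 0) and tests the Wald p of that single score. Nonlinearity is
tested with a 4-knot restricted cubic spline (truncated-power natural
basis, knots at the 5/35/65/95 percentiles, linear term first so the
nonlinear block is testable). Proportional hazards are checked by the
Grambsch–Therneau scaled-Schoenfeld score test plus an attained-age
interaction refit, in which follow-up is split into 1-year episodes so a
$x \times \log(\text{age})$ product can be evaluated at the episode age;
log(−log) survival curves are emitted as plot data only.

# Bootstrap and imputation

The BCa bootstrap resamples subjects with replacement, independently in the
cohort and the substudy, and by default refits the calibration model in
every replicate so the interval carries first-stage uncertainty
(`refit_calibration = FALSE` freezes stage 1; the published description
does not say which was done, so both are implemented). Bias correction
$z_0$ comes from the replicate fraction below the point estimate;
acceleration $a$ from jackknife skewness — leave-one-subject-out at small
$n$, a 50-group delete-a-group approximation above 2000 rows, where
leave-one-out would dominate runtime without changing $a$ appreciably (the
test suite compares the two on moderate $n$). With $z_0 = a = 0$ the
interval is exactly the percentile interval. The reference analysis uses
$B = 4000$; the pipeline default exercises smaller $B$ for tractability and
the full 4000 remains a parameter.

Missing covariates are imputed by chained equations: Bayesian linear
regression with predictive-mean matching (5 donors) for continuous
variables, weighted-bootstrap logistic/multinomial draws for categorical
ones, $m = 5$ imputations. Only covariates are ever imputed; exposures,
ages, events and the structurally missing cause-of-death code are
excluded. Pooling follows Rubin's rules on the log-HR scale
($T = W + (1 + 1/m)B$, Rubin's small-sample df), exponentiating
afterwards. When the pipeline combines imputation with the bootstrap, the
BCa interval is computed on the first completed data set — a pragmatic
choice, recorded here, since nesting $B$ bootstrap rounds inside $m$
imputations is rarely worth the cost at these missingness levels (~2–4%).

# Population attributable risk

Levin's formula, $\mathrm{PAR} = p(\mathrm{HR}-1)/(1 + p(\mathrm{HR}-1))$,
with $p$ the fraction of subjects at or above the 90th-percentile contrast
exposure and HR the calibrated contrast estimate. The formula behind the
published attributable-risk values is not printed in the source analyses;
Levin's form with this exposed fraction is our declared choice and is
labelled as such in the report.

# The synthetic cohort generator

The generator is the package's test bed: it produces cohorts with the
statistical structure the analysis assumes, plus the ground truth needed
for recovery tests (`truth` is never consumed by analysis code).

- **Exposures.** True usual intakes for unprocessed red meat, processed
  meat, poultry and fish follow zero-inflated log-normal marginals coupled
  by a Gaussian copula. Defaults: zero-mass 0.646 (red) and 0.667
  (processed), matching a cohort where roughly two-thirds report zero;
  consumer medians near 12 and 2 g/day with quartile spreads matching the
  published quartile medians; red–processed Pearson correlation 0.56. The
  latent copula correlation is solved numerically (Gauss–Hermite
  quadrature of the transformed-bivariate-normal moment) so the *realised*
  Pearson correlation of intakes hits the target; infeasible targets are
  rejected with the attainable bound named. The joint distribution of diet
  with covariates is independent by default — the source material gives
  only marginal summaries — with an optional smoking–intake latent shift
  for confounding experiments.
- **Measurement.** FFQ = truth × mean-one log-normal error for consumers
  (zero reporters are exact); the error SD is set from the target validity
  correlation via `ffq_error_for_validity()` (defaults 0.74 red, 0.43
  processed on the log-consumer scale). A 1000-subject substudy receives
  six recall replicates with independent within-person error. A Gaussian
  (`family = "normal"`, additive-error) mode supports methodological
  validation runs where exact classical-error theory applies.
- **Survival.** Weibull baseline on the age scale (shape 8, scale 101),
  sampled by inverse transform conditional on survival to the entry age,
  which makes the conditional survivor function available in closed form
  for a Kolmogorov–Smirnov oracle test. Entry ages are truncated-normal
  (57 ± 14, range 25–90); follow-up is 11.8 ± 2.5 years (a 5-year accrual
  window with a fixed cut-off). These settings yield ~11% deaths, the
  event fraction of the emulated study. Causes are drawn as ICD-10-like
  code strings (32.6% CVD, 23.5% cancer, 3% unnatural among deaths) so the
  analysis-side classifier is genuinely exercised.
- **Missingness.** Per-covariate MAR: the missingness logit depends on
  entry age and sex only, with the intercept solved so the realised rate
  matches the configuration.
- **Reproducibility.** One master seed feeds fixed per-stage streams
  (exposures, measurement, survival, missingness, imputation, bootstrap),
  so any sub-table can be regenerated in isolation and identical
  configurations are byte-identical.

**What the generator does not emulate.** Zero reporters are error-free by
construction, so with two-thirds of the cohort at an exact zero the
*overall* FFQ reliability is much higher than the consumer-scale validity
correlations suggest; under these default conditions regression calibration
moves hazard ratios only modestly. The strong calibrated-versus-naive
divergence reported for real cohorts is reproduced instead under the
generator's Gaussian validation mode at reliability 0.5, where classical
error theory holds exactly. Recalls are log-normal around the truth —
real 24-h recalls of episodically eaten foods are zero on most days.
Diet–covariate confounding is off by default. Passing tests therefore
demonstrate correctness of the estimators under their stated error models,
not fidelity of any particular published effect size.

# Numerical choices

- Newton–Raphson converges on the Newton decrement relative to the loglik
  magnitude (with one polishing step), since at large $n$ the partial
  likelihood is computed to rounding noise that a fixed gradient tolerance
  would chase forever; standardised coefficients beyond ±12 raise a
  monotone-likelihood (separation) error; singular information is reported
  as collinearity, never silently dropped.
- The risk-set sweep adds and removes subjects incrementally
  ($O(n\log n + np^2)$); subjects entering at or after the last event age
  are dropped up front, which also makes fits bit-identical under their
  inclusion.
- Efron tie handling is the default (ages are coarsely recorded);
  Breslow is selectable.
- Quartile cut-points use type-7 quantiles; degenerate categorisations
  (fewer than 4 distinct consumer values, cut-points collapsing at zero)
  are errors, not warnings.
- Strata with fewer than 30 events in subgroup analyses are flagged
  `low_information` (and unfittable strata return NA) rather than dropped.

# Problem sizes in the test battery

The packaged validation uses, as its own design choice: oracle agreement
at $n = 200$; attenuation/recovery at $n = 20{,}000$ with a 1000-subject
substudy over 200 replicates; BCa coverage over 500 simulations at
$B = 2000$; pooled-CI coverage over 500 MAR simulations; test-size
calibration over 500 null simulations at $n = 1500$; and generator
convergence checks at $n = 50{,}000$. `scripts/acceptance.R` re-runs the
study-scale pipeline at $n = 20{,}000$ with $m = 5$ and $B = 200$.

# Known limitations

Calibration is single-exposure (no multivariate simultaneous calibration,
no SIMEX); covariates are fixed at baseline (the attained-age scale is the
only "time-dependence"); competing risks are handled by cause-specific
censoring, not subdistribution models; and the Wald interval reported for
calibrated contrasts without the bootstrap ignores first-stage uncertainty
— use the BCa branch when that matters.
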
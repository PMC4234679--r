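---
title: "Two-part regression calibration for episodically consumed foods: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part regression calibration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement-error problem and the correction

Let `T` be a subject's true usual intake of an episodically consumed food
(g/day), `Q` the questionnaire measurement, `R` a single-day reference
measurement available only in a calibration sub-study, and `Z` the disease
confounders. The disease model of interest is a Cox proportional hazards
model for mortality with linear predictor `beta * T/100 + gamma' Z`,
stratified by center and sex. Random error in `Q` attenuates the naive
estimate of `beta`; regression calibration replaces `Q` by an estimate of
`E[T | Q, X]` (where `X` is `Q`, the confounders, and covariates that
predict intake only) and refits the disease model.

Two assumptions carry the method:

1. **Unbiased reference**: `E[R | subject] = T`. For a single-day recall of
   an episodic food this means the zeros and the positive amounts must
   *jointly* average to usual intake.
2. **Non-differential error**: `Q` tells you nothing about the outcome
   beyond `T`.

Because `R` has a point mass at zero (non-consumption days) and skewed,
heteroscedastic positive amounts, `E[R | X]` is modelled in two parts:

* Part I, consumption probability: binomial GLM, logit link, response
  `1{R > 0}`.
* Part II, amount on consumption occasions: gamma GLM, log link, response
  `R` on the consumers-only subset.

The calibrated exposure is the product of the two fitted means. Since
`E[R | X] = P(R > 0 | X) * E[R | R > 0, X]` identically, the product
targets `E[T | X]` whenever the reference is unbiased — no person-level
variance components are needed, which is what makes the approach feasible
with one replicate per subject. The price is that any residual correlation
between a subject's consumption propensity and their consumed amount cannot
be estimated or used; covariates shared by the two parts absorb it only
partly. The synthetic-data generator exposes this correlation as a dial
(`re_correlation`) precisely so that users can stress the method against
it; the calibration model itself ignores it by design.

## Choosing the GLM family and the form of Q

Two exploratory tools guide the specification:

**Variance–mean diagnostic** (`variance_mean_slope`). Under a
power-proportional variance function `Var = kappa^2 * mean^lambda`, the
regression of group-level `log(SD)` on `log(mean)` has slope `lambda / 2`.
We estimate the slope by OLS across centers (consumers only) and read
`lambda = 2 * slope`: 0 means constant variance, 1 Poisson-like, 2
gamma-like (SD proportional to the mean). The package maps `lambda_hat` to a
family suggestion with midpoint bands (`[-0.5, 0.5)` constant,
`[0.5, 1.5)` Poisson-like, `[1.5, 2.5]` gamma-like); the anchors are the
standard ones and the bands are a deterministic, documented choice. Groups
with fewer than `min_group_n = 10` observations are excluded from the
regression (small-group SDs are too unstable to help); the graphical
estimator is used deliberately — it is transparent, and its simplicity is
the point — rather than maximum likelihood for `lambda`.

**Empirical logit and transform selection** (`empirical_logit_curve`,
`select_transform`). The curve bins Q into the exact-zero category followed
by fixed-width intervals (default 10 g/day) and computes
`ln((y + 0.5) / (n - y + 0.5))` per bin; the +0.5 continuity correction
keeps boundary bins finite and minimises log-odds bias. The shape of the
curve (and of a penalized-regression-spline partial prediction, smoothing
parameter chosen by GCV through `mgcv`) suggests candidate parametric forms
of Q; the final choice among identity, square root and `log(Q + 1)` is by
AIC of the part-appropriate GLM, with ties broken toward the simpler
transform (identity < sqrt < log). The `+1` offset inside the log keeps
never-consumers (`Q = 0`) in the model; the offset is configurable. The
loess span used when plotting the curve is visual-only and exposed as a
parameter (default 0.75).

## Covariate sets, reduction, extreme predictions

The "standard" specification (`build_standard_specs`) contains the eight
disease-model confounders (BMI, smoking status, physical activity, lifetime
alcohol, education, age, total energy, sex), the intake predictors season,
center and body weight, transformed Q, two-way interactions of transformed Q
with sex, age, season, BMI and center, and a quadratic age term in the
amount part only. Because every covariate enters twice (once per part), the
standard model is prone to overfitting; `backward_eliminate` produces the
"reduced" form by removing, one at a time, the least significant removable
term by a joint Wald chi-square (categorical terms tested jointly — one
test per factor, keeping factors intact) until everything retained has
p < 0.2. The permissive level is deliberate: the cost of dropping a true
predictor of intake (bias) exceeds the cost of keeping a useless one
(variance). Hierarchy rules: transformed Q is never removable; a main effect
can leave only after every interaction containing it (and, for age, the
quadratic term) has left.

Predictions are made for the whole cohort; any prediction above five times
the 99th percentile of all predictions is flagged as unrealistic and
excluded from the disease model. This filter exists because models with
untransformed skewed Q — especially with Q-by-covariate interactions and a
log link — can extrapolate explosively outside the calibration sample's
covariate space. Flagged counts are reported, and the filter is defined on
predictions, so the naive (Q-based) fit is never filtered.

Part-I fit quality is summarised by the ROC AUC (rank-statistic
formulation, midranks for ties), Part II by RMSE and mean bias on
consumers. These are computed in-sample by default, matching how such
summaries are usually reported for calibration models; a held-out
`calibration_table` of identical schema can be passed instead.

## Uncertainty propagation

Plugging a fitted prediction into the Cox model understates the standard
error: the calibration coefficients are themselves estimated. The package
bootstraps the calibration sub-study (resampling within center, keeping the
main study fixed — the calibration sample is the only place estimation
noise enters the exposure), refits the two-part model, re-predicts,
re-filters and refits the Cox model per replicate, then combines by the
multiple-imputation rule: pooled estimate = mean of replicate estimates,
total variance `W + (1 + 1/m) B` with `W` the mean squared within-replicate
SE and `B` the between-replicate variance (divisor `m - 1`). The ratio of
total SE to within-only SE (always >= 1 in this combination) is the
headline diagnostic of how much uncertainty the naive SE misses. The
default is `m = 25` for production use; the package's own simulation tests
use `m = 12` (sufficient for a stable `B` at test problem sizes). The
full-sample single-fit estimate is also reported by `run_pipeline` for
comparison; replicate-level fit failures are dropped and counted, with more
than 20% failures an error.

## What the synthetic generator emulates — and what it does not

The generator is truth-first: covariates are drawn per subject;
person-level effects `(u, v)` (SDs `prob_re_sd`, `amount_re_sd`,
correlation `re_correlation`) enter the consumption-probability logit and
the log usual amount; `pi_i = expit(lp_prob)`, `A_i = exp(lp_amount)`, and
true usual intake is `T_i = pi_i * A_i`. The reference is
`R_i = Bernoulli(pi_i) * Gamma(mean A_i, shape)`, so `E[R_i] = T_i` holds
by construction — the generator realises exactly the regime in which
regression calibration is consistent. The questionnaire is
`Q_i = max(0, a + b T_i + bias_i + noise_i)` with an additional
never-reporter point mass at zero concentrated on subjects with genuinely
low consumption probability (Bernoulli with probability proportional to
`(1 - pi_i)^3`, scaled to the target fraction). That concentration matters:
it is what produces the steep-then-flat empirical-logit shape seen in real
dietary data, under which a log-transformed Q is the appropriate Part-I
form. Survival times are exponential with hazard
`h0 * exp(beta T/100 + gamma' Z)`; censoring is independent exponential
with its rate set from the mean event hazard so the realized censored
fraction approximates `censoring_rate` (approximate by design — any
independent censoring mechanism is valid for the recovery tests), plus
administrative censoring at 15 years.

Default regime (the `"default"` preset, checked by the test suite):
reference zero fraction ~0.50, corr(Q, R) ~0.3, positive-amount skewness
~3, mean usual intake ~55 g/day, true log hazard ratio −0.50 per 100 g/day,
~14% events. The `"frequent"` and `"rare"` presets move the zero fraction
toward ~0.35 and ~0.75; `"noiseless"` makes Q = T for limiting-case tests;
`"skewed"` couples the two person-level effects tightly (correlation 0.95
within the preset's heavier-tailed amounts) and tightens the questionnaire
noise, producing a log-linear truth under which an untransformed-Q
calibration model is materially misspecified.

What the generator does **not** emulate: real questionnaires' systematic,
intake-dependent and correlated errors (here Q-errors are classical,
additive, independent of R's errors — exactly the assumptions of the
method, which real 24-hour recalls violate to a degree); country-specific
instruments and food-composition differences; missing data; competing
risks; and any within-person day-to-day correlation structure beyond the
single `re_correlation` dial. Passing tests therefore demonstrate that the
implementation corrects the error structure it assumes, not that those
assumptions hold for any particular real instrument.

A seed-substream policy (one master seed, a fixed sub-stream per generation
stage) makes every table reproducible byte for byte and keeps earlier
stages invariant when later stages are added.

## Numerical choices

* GLMs are fitted by IRLS with relative deviance tolerance 1e-12 and at
  most 100 iterations; at looser tolerances the gamma part can stop a few
  parts in 1e5 away from the exact MLE on small samples.
* The gamma/log IRLS (whose update weights are identically 1) can enter a
  limit cycle on heavily skewed amounts with rich designs; the package
  first runs IRLS with step halving on the deviance and hands the converged
  coefficients to `glm()` as starting values, so the returned object is a
  standard `glm` fit evaluated at the optimum. Linear predictors are capped
  at 700 inside the step-halving search to avoid overflow.
* Gamma dispersion is the Pearson estimate; it affects standard errors
  only, never predictions.
* Complete separation in Part I is detected (all fitted probabilities at
  the boundary) and reported with the runaway covariate named.
* Cox models use the Efron tie approximation.
* The extreme-prediction threshold uses the default (type-7) sample
  quantile.
* One-part linear predictions may be negative; they are kept, counted and
  reported, never truncated.
* AIC ties in transform selection (difference below 1e-8) go to the
  simpler transform.
* Backward elimination tests factors jointly (one Wald chi-square on all
  coefficients of a term) rather than level-wise, keeping factors intact.
* Event-free categories in the hazard-ratio curve are merged downward with
  a warning; the reference category's log HR is exactly 0 by convention.

## Problem sizes used by the test suite

The simulation-based tests run at deliberately reduced sizes chosen so the
statistical properties under test are identifiable yet the suite stays
quick: end-to-end recovery uses 100 cohorts of `n_main = 6000`,
`n_calib = 2000` with `m = 12` bootstrap replicates; the misspecification
ordering uses 50 cohorts of the `"skewed"` preset; the elimination-level
check uses 200 replicates at `n = 5000`; Monte-Carlo checks of generator
unbiasedness use `n = 1e5`. The default production-scale preset
(`n_main = 20000`, `n_calib = 2000`, `m = 25`) runs the full pipeline in a
few minutes on one CPU.

## Known limitations

* With one replicate per subject the correlation between consumption
  propensity and amount is unidentifiable; if it is strong and the shared
  covariates absorb little of it, the calibrated estimate can retain bias.
* Regression calibration in a Cox model is itself an approximation
  (exact only in the rare-event, small-effect limit); at large effect
  sizes a residual bias remains even with a perfectly specified
  calibration model.
* The bootstrap propagates calibration-sampling uncertainty only; main
  study sampling enters through the within-replicate Cox SE, and the two
  are combined as if independent.
* The pooled bootstrap estimate can be slightly more attenuated than the
  full-sample fit in small calibration samples (resampling amplifies
  overfitting); both are reported.
* Backward elimination inherits the usual caveats of stepwise selection;
  it is provided because reducing the double-entered covariate set
  demonstrably improves the correction, not as a general-purpose variable
  selector.
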
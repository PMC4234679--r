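# twopartRC

Two-part regression calibration for episodically consumed foods in
single-replicate calibration designs.

## The problem

Nutritional cohort studies measure diet with questionnaires (Q) that carry
substantial random error, which attenuates the estimated association between
intake and disease toward the null. Regression calibration corrects this by
replacing Q in the disease model with a prediction of true usual intake T
given Q and error-free covariates, fitted in a calibration sub-study where an
unbiased short-term reference measurement R (a 24-hour recall) is available.

For *episodically consumed* foods — vegetables, fish, anything not eaten
daily — a single-day reference measurement is zero for every subject who did
not consume the food that day. The reference is then a mixture of excess
zeros and right-skewed, heteroscedastic positive amounts, and the usual
one-part linear calibration model is badly misspecified. When each
calibration subject has only **one** reference measurement, person-level
variance components cannot be estimated, so mixed-model approaches developed
for replicated designs do not apply either.

`twopartRC` implements the single-replicate two-part (hurdle) calibration
model and everything around it:

* **Part I** — probability of consumption: binomial GLM, logit link, on
  `1{R > 0}`:  `logit P(R_i > 0) = alpha' x_i`
* **Part II** — amount on consumption occasions: gamma GLM, log link, on
  `R | R > 0`:  `log E[R_i | R_i > 0] = gamma' x_i`
* **Prediction** (the calibrated exposure):
  `T_hat_i = expit(alpha' x_i) * exp(gamma' x_i)`
* **Disease model**: Cox proportional hazards of all-cause mortality on
  `T_hat / 100`, adjusted for confounders and stratified by center and sex,
  so the coefficient is a log hazard ratio per 100 g/day.
* **Diagnostics**: the variance–mean power diagnostic
  (`Var = kappa^2 mean^lambda`, lambda estimated as twice the OLS slope of
  log SD on log mean across centers), continuity-corrected empirical logit
  curves `ln((y+0.5)/(n-y+0.5))`, and AIC selection among identity / sqrt /
  log transforms of Q with penalized-spline visual confirmation.
* **Model reduction**: backward elimination at alpha = 0.2 with joint Wald
  tests per term, hierarchy rules, and a non-removable Q term.
* **Extreme-prediction filter**: predictions above five times their 99th
  percentile are flagged and excluded from the disease model.
* **Uncertainty**: center-stratified bootstrap of the calibration sub-study,
  refitting calibration + disease model per replicate, combined by Rubin's
  rule `total variance = W + (1 + 1/m) B`.
* **Synthetic cohorts**: a generator with known ground truth (true log
  hazard ratio, consumption probabilities, usual amounts) emulating the
  zero-inflation, skewness, weak Q–R correlation and center structure of
  multicenter dietary data, so the whole workflow is testable end to end.

## Worked example

Simulate a cohort whose true log hazard ratio is −0.50 per 100 g/day, with a
biased noisy questionnaire and a single 24-hour-recall-style reference
measurement for 2,000 of 6,000 subjects:

```r
library(twopartRC)

cfg    <- generator_preset("default", n_main = 6000, n_calib = 2000, seed = 1)
cohort <- generate_cohort(cfg)
calib  <- draw_reference(cohort, cfg)
calib
#> <calibration_table> 2000 subjects, 8 centers, 287 events (14.3%)
#>   reference zero fraction: 54.3%
#>   Q: mean 51.9 g/day, 19.4% zero
```

The variance–mean diagnostic on the positive amounts points at a gamma
family (SD proportional to the mean, lambda near 2):

```r
pos <- calib[calib$R > 0, ]
variance_mean_slope(pos$R, pos$center, min_group_n = 30)
#> Variance-mean diagnostic: slope 1.126 (SE 0.132), lambda-hat 2.252 -> gamma-like
```

The naive Cox fit on Q is attenuated; the reduced two-part calibration
recovers an estimate close to the truth, and the bootstrap shows the naive
SE understates the uncertainty:

```r
conf <- c("bmi", "smoking_status", "physical_activity", "alcohol",
          "education", "age", "energy")

naive_association(cohort, conf, c("center", "sex"))
#> Cox PH: log HR -0.3754 (SE 0.0806) per 100 g/day usual intake

specs <- build_standard_specs()
red1  <- backward_eliminate(calib, specs$probability)
red2  <- backward_eliminate(calib, specs$amount)
fit   <- fit_two_part(calib, red1, red2)
score_fit(fit, calib)
#> Part I AUC 0.6335; Part II RMSE 121.107 g/day, mean bias -0.3163 g/day (914 consumers)

pred <- predict_usual_intake(fit, cohort)
fit_cox(cohort, pred$predicted, conf, c("center", "sex"), exclude = pred$extreme)
#> Cox PH: log HR -0.6705 (SE 0.1725) per 100 g/day usual intake

run <- bootstrap_calibrated_association(calib, cohort, red1, red2,
                                        m = 12, seed = 2, confounders = conf)
rubin_combine(run)
#> Pooled log HR -0.6022 per 100 g/day (m = 12 replicates)
#>   within SE 0.1636, between var 0.00456, total SE 0.1781 (SE ratio 1.09)
```

Reading the output: the questionnaire-only estimate (−0.38) is roughly 25%
smaller in magnitude than the truth (−0.50); the calibrated pooled estimate
(−0.60 ± 0.18) covers it; and the Rubin-combined SE exceeds the
within-replicate SE because calibration uncertainty is propagated. The
`run_pipeline()` function assembles the same workflow — plus the one-part
linear and untransformed-Q comparators in standard and reduced forms — into
a single comparison report.

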
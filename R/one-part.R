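#' Fit the one-part linear calibration comparator
#'
#' The calibration model historically used by epidemiologists: ordinary
#' least squares of the reference measurement R (zeros included) on
#' untransformed Q and the adjustment covariates, under the classical
#' assumptions of normality and homoscedasticity. For episodically consumed
#' foods both assumptions are violated -- the response has a point mass at
#' zero and the positive amounts are right-skewed and heteroscedastic -- so
#' this model serves as the benchmark the two-part model is compared
#' against. Predictions may be negative; they are reported, not truncated,
#' and counted.
#'
#' @param calib A `calibration_table`.
#' @param spec A [model_spec()] with `part = "one_part"` (transform
#'   `"identity"` for the classical comparator).
#' @return An object of class `one_part_fit` carrying the `lm` fit,
#'   coefficients and covariance.
#' @export
fit_one_part <- function(calib, spec) {
  if (nrow(calib) == 0) stop("calibration table is empty", call. = FALSE)
  if (!"R" %in% names(calib))
    stop("calibration table must contain the reference measurement R",
         call. = FALSE)
  if (spec$part != "one_part")
    stop("spec must have part = 'one_part'", call. = FALSE)
  d <- prepare_model_frame(spec, calib)
  fit <- stats::lm(spec_formula(spec, "R"), data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design: aliased columns ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  structure(list(coefficients = cf, vcov = stats::vcov(fit), fit = fit,
                 spec = spec, n = nrow(calib)),
            class = "one_part_fit")
}

#' @export
print.one_part_fit <- function(x, ...) {
  cat(sprintf("<one_part_fit> OLS of R on %d terms, n = %d\n",
              length(x$coefficients), x$n))
  invisible(x)
}

#' Predict usual intake from the one-part linear calibration model
#'
#' The linear fit evaluated at each subject's Q and covariates. Negative
#' predictions are kept (with a count in the attributes and a warning), and
#' the same fivefold-99th-percentile extreme flag as the two-part model is
#' applied.
#'
#' @param fit A [fit_one_part()] result.
#' @param cohort A `cohort_table`.
#' @param extreme_multiplier Multiplier of the 99th percentile defining the
#'   extreme threshold (default 5).
#' @return A `prediction_result` data.frame (`subject_id`, `predicted`,
#'   `extreme`) with attributes `threshold`, `n_flagged`, `n_negative`.
#' @export
predict_one_part <- function(fit, cohort, extreme_multiplier = 5) {
  check_factor_levels(fit$fit, cohort)
  d <- prepare_model_frame(fit$spec, cohort)
  pred <- as.numeric(stats::predict(fit$fit, newdata = d))
  n_neg <- sum(pred < 0)
  if (n_neg > 0)
    warning(sprintf("%d negative predicted intakes from the one-part linear model (kept, not truncated)",
                    n_neg), call. = FALSE)
  threshold <- extreme_multiplier * stats::quantile(pred, 0.99, names = FALSE)
  extreme <- pred > threshold
  out <- data.frame(subject_id = cohort$subject_id, predicted = pred,
                    extreme = extreme, stringsAsFactors = FALSE)
  structure(out, threshold = threshold, n_predicted = nrow(out),
            n_flagged = sum(extreme), n_negative = n_neg,
            extreme_multiplier = extreme_multiplier,
            class = c("prediction_result", "data.frame"))
}
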
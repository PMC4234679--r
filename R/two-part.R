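#' Fit the two-part (hurdle) calibration model
#'
#' Part I models the probability of any consumption as reported on the
#' reference instrument, `1{R > 0}`, by a binomial GLM with logit link.
#' Part II models the consumed amount on consumption occasions, `R` among
#' subjects with `R > 0`, by a gamma GLM with log link (chosen to stabilise
#' the variance and guarantee positive predictions). Both parts are fitted
#' by iteratively reweighted least squares with convergence tolerance 1e-12
#' on the relative deviance change and at most 100 iterations. The gamma
#' dispersion is estimated from the Pearson statistic (it affects standard
#' errors only, not predictions).
#'
#' @param calib A `calibration_table` (must contain at least one consumer
#'   and one non-consumer; at least two consumers).
#' @param spec1 A [model_spec()] with `part = "probability"`.
#' @param spec2 A [model_spec()] with `part = "amount"`.
#' @return An object of class `two_part_fit` with components `part1` and
#'   `part2` (each carrying coefficients, covariance, family metadata,
#'   convergence info, and the underlying `glm` fit) and the two specs.
#' @export
fit_two_part <- function(calib, spec1, spec2) {
  if (nrow(calib) == 0) stop("calibration table is empty", call. = FALSE)
  if (!"R" %in% names(calib))
    stop("calibration table must contain the reference measurement R",
         call. = FALSE)
  if (spec1$part != "probability")
    stop("spec1 must have part = 'probability'", call. = FALSE)
  if (spec2$part != "amount")
    stop("spec2 must have part = 'amount'", call. = FALSE)

  consumed <- calib$R > 0
  if (all(consumed) || !any(consumed))
    stop(sprintf(
      "part 1 needs both consumers and non-consumers; got %d consumers of %d",
      sum(consumed), length(consumed)), call. = FALSE)
  if (sum(consumed) < 2)
    stop("part 2 needs at least 2 consumers (R > 0)", call. = FALSE)

  d1 <- prepare_model_frame(spec1, calib)
  f1 <- stats::glm(spec_formula(spec1, "consumed"),
                   family = stats::binomial("logit"), data = d1,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  check_convergence(f1, "part 1 (consumption probability)")
  check_separation(f1)

  d2 <- prepare_model_frame(spec2, calib[consumed, , drop = FALSE])
  f2 <- fit_gamma_log(spec_formula(spec2, "R"), d2)
  check_convergence(f2, "part 2 (consumed amount)")
  dispersion <- sum(stats::residuals(f2, type = "pearson")^2) / f2$df.residual

  structure(list(
    part1 = list(coefficients = stats::coef(f1), vcov = stats::vcov(f1),
                 family = "binomial", link = "logit", fit = f1,
                 iterations = f1$iter, spec = spec1),
    part2 = list(coefficients = stats::coef(f2), vcov = stats::vcov(f2),
                 family = "Gamma", link = "log", dispersion = dispersion,
                 fit = f2, iterations = f2$iter, spec = spec2),
    n = nrow(calib), n_consumers = sum(consumed)
  ), class = "two_part_fit")
}

# Gamma GLM with log link. Plain IRLS can enter a limit cycle on heavily
# skewed amounts with rich designs, so run IRLS with step halving on the
# deviance first (for this family/link the IRLS weights are identically 1,
# so each update is an OLS of the working response), then hand the converged
# coefficients to glm() as starting values so the returned object is a
# standard glm fit evaluated at the optimum.
fit_gamma_log <- function(formula, data, tol = 1e-12, maxit = 100) {
  ctrl <- stats::glm.control(epsilon = tol, maxit = maxit)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  beta <- irls_gamma_log(X, y, tol = tol, maxit = maxit)
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::Gamma("log"), data = data,
               start = beta, control = ctrl))
  if (!fit$converged)   # fall back to the canonical starting values
    fit <- suppressWarnings(
      stats::glm(formula, family = stats::Gamma("log"), data = data,
                 control = ctrl))
  fit
}

gamma_deviance <- function(y, mu) 2 * sum(-log(y / mu) + (y - mu) / mu)

irls_gamma_log <- function(X, y, tol = 1e-12, maxit = 100) {
  qx <- qr(X)
  beta <- qr.coef(qx, log(y))
  beta[is.na(beta)] <- 0
  dev <- gamma_deviance(y, exp(drop(X %*% beta)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- qr.coef(qx, z)
    beta_new[is.na(beta_new)] <- 0
    dev_new <- gamma_deviance(y, exp(pmin(drop(X %*% beta_new), 700)))
    halvings <- 0
    while ((!is.finite(dev_new) || dev_new > dev + 1e-12) && halvings < 30) {
      beta_new <- (beta_new + beta) / 2
      dev_new <- gamma_deviance(y, exp(pmin(drop(X %*% beta_new), 700)))
      halvings <- halvings + 1
    }
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    beta <- beta_new
    dev <- dev_new
    if (done) break
  }
  beta
}

check_convergence <- function(fit, label) {
  if (!fit$converged)
    stop(sprintf("%s did not converge after %d IRLS iterations (deviance %.6g)",
                 label, fit$iter, fit$deviance), call. = FALSE)
  invisible(fit)
}

# Complete separation makes logistic coefficients diverge; flag the term
# whose coefficient ran away.
check_separation <- function(fit) {
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (all(p < eps | p > 1 - eps)) {
    worst <- names(which.max(abs(stats::coef(fit))[-1]))
    stop(sprintf(
      "complete separation in the consumption probability part (covariate '%s')",
      worst), call. = FALSE)
  }
  invisible(fit)
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat(sprintf("<two_part_fit> n = %d (%d consumers, %.1f%%)\n",
              x$n, x$n_consumers, 100 * x$n_consumers / x$n))
  cat(sprintf("  part 1: binomial(logit), %d coefficients, %d IRLS iterations\n",
              length(x$part1$coefficients), x$part1$iterations))
  cat(sprintf("  part 2: Gamma(log), %d coefficients, dispersion %.3f\n",
              length(x$part2$coefficients), x$part2$dispersion))
  invisible(x)
}

#' Predict usual intake for main-study subjects
#'
#' The regression-calibration prediction of true usual intake is the product
#' of the two fitted parts evaluated at each subject's questionnaire
#' measurement and covariates:
#' `prediction = inverse-logit(x' beta1) * exp(x' beta2)` -- the probability
#' of consumption times the expected amount on consumption occasions.
#' Predictions exceeding five times the 99th percentile of all predictions
#' are flagged as unrealistic extremes; downstream disease-model fits
#' exclude flagged subjects.
#'
#' @param fit A [fit_two_part()] result.
#' @param cohort A `cohort_table` whose covariates cover every model term.
#' @param extreme_multiplier Multiplier of the 99th percentile defining the
#'   extreme-prediction threshold (default 5).
#' @return An object of class `prediction_result`: a data.frame with
#'   `subject_id`, `predicted` (g/day), `p_consumption`, `amount`, and
#'   `extreme`; attributes `threshold`, `n_predicted`, `n_flagged`.
#' @export
predict_usual_intake <- function(fit, cohort, extreme_multiplier = 5) {
  check_factor_levels(fit$part1$fit, cohort)
  check_factor_levels(fit$part2$fit, cohort)
  d1 <- prepare_model_frame(fit$part1$spec, cohort)
  d2 <- prepare_model_frame(fit$part2$spec, cohort)
  p <- stats::predict(fit$part1$fit, newdata = d1, type = "response")
  mu <- stats::predict(fit$part2$fit, newdata = d2, type = "response")
  pred <- as.numeric(p * mu)
  threshold <- extreme_multiplier * stats::quantile(pred, 0.99, names = FALSE)
  extreme <- pred > threshold
  out <- data.frame(subject_id = cohort$subject_id, predicted = pred,
                    p_consumption = as.numeric(p), amount = as.numeric(mu),
                    extreme = extreme, stringsAsFactors = FALSE)
  structure(out, threshold = threshold, n_predicted = nrow(out),
            n_flagged = sum(extreme), extreme_multiplier = extreme_multiplier,
            class = c("prediction_result", "data.frame"))
}

check_factor_levels <- function(fit, newdata) {
  xl <- fit$xlevels
  for (v in names(xl)) {
    seen <- unique(as.character(newdata[[v]]))
    unseen <- setdiff(seen, xl[[v]])
    if (length(unseen))
      stop(sprintf("covariate '%s' has levels unseen at fit time: %s (fitted levels: %s)",
                   v, paste(unseen, collapse = ", "),
                   paste(xl[[v]], collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Evaluate the fit of a two-part calibration model
#'
#' Part I is scored by the area under the ROC curve of the predicted
#' consumption probabilities against the observed consumption indicator,
#' computed by the rank-statistic (Mann-Whitney) formulation with midranks
#' for ties. Part II is scored on consumers only by the root mean squared
#' error and the mean bias of the conditional-mean amount prediction.
#'
#' @param fit A [fit_two_part()] result.
#' @param calib The fitting sample or a held-out `calibration_table` of
#'   identical schema.
#' @return An object of class `fit_score` with `auc`, `rmse` (g/day) and
#'   `mean_bias` (g/day).
#' @export
score_fit <- function(fit, calib) {
  if (!any(calib$R > 0))
    stop("no consumers in the evaluation sample: RMSE and mean bias undefined",
         call. = FALSE)
  d1 <- prepare_model_frame(fit$part1$spec, calib)
  p <- stats::predict(fit$part1$fit, newdata = d1, type = "response")
  auc <- auc_rank(p, calib$R > 0)

  cons <- calib$R > 0
  d2 <- prepare_model_frame(fit$part2$spec, calib[cons, , drop = FALSE])
  mu <- stats::predict(fit$part2$fit, newdata = d2, type = "response")
  r <- calib$R[cons]
  structure(list(auc = auc, rmse = sqrt(mean((r - mu)^2)),
                 mean_bias = mean(mu - r), n_consumers = sum(cons)),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf("Part I AUC %.4f; Part II RMSE %.3f g/day, mean bias %.4f g/day (%d consumers)\n",
              x$auc, x$rmse, x$mean_bias, x$n_consumers))
  invisible(x)
}

# Mann-Whitney AUC: midranks handle ties, equivalent to the all-pairs
# concordance count with ties scoring 1/2.
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both positive and negative labels", call. = FALSE)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
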
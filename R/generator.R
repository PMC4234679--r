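#' Generate a synthetic main-study cohort
#'
#' Simulates a multicenter cohort with known ground truth. For each subject
#' the generator draws demographic and lifestyle covariates, builds the
#' individual consumption probability `pi_i` (logistic scale) and usual
#' positive amount `A_i` (log scale, g/day) from covariates, center effects
#' and correlated person-level random effects, and sets true usual intake
#' `T_i = pi_i * A_i`. The questionnaire measurement is
#' `Q_i = max(0, a + b * T_i + bias_i + noise_i)` with an independent
#' never-reporter point mass at zero. Survival times come from an
#' exponential baseline whose hazard is multiplied by
#' `exp(true_log_hr_per100g * T_i / 100 + gamma' Z_i)`, with independent
#' exponential censoring calibrated to the configured censoring rate and
#' administrative censoring at 15 years.
#'
#' The returned table keeps the hidden truth columns (`T`, `pi_true`,
#' `amount_true`) so downstream recovery can be tested; a real cohort would
#' not have them.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `cohort_table`, one row per subject.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_main

  # stage 1: covariates
  set.seed(substream_seed(config$seed, 1L))
  center <- factor(sprintf("C%02d", sample.int(config$n_centers, n, replace = TRUE)),
                   levels = sprintf("C%02d", seq_len(config$n_centers)))
  country <- factor(sprintf("country%d", (as.integer(center) - 1L) %/% 2L + 1L))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
  age <- stats::runif(n, 35, 70)
  bmi <- pmax(16, stats::rnorm(n, 26, 4))
  smoking_status <- factor(sample(c("never", "former", "current"), n,
                                  replace = TRUE, prob = c(0.45, 0.3, 0.25)),
                           levels = c("never", "former", "current"))
  physical_activity <- factor(sample(c("inactive", "mod_inactive",
                                       "mod_active", "active"), n,
                                     replace = TRUE,
                                     prob = c(0.2, 0.3, 0.3, 0.2)),
                              levels = c("inactive", "mod_inactive",
                                         "mod_active", "active"))
  alcohol <- stats::rgamma(n, shape = 1.2, scale = 10)
  education <- factor(sample(c("none", "primary", "technical", "secondary",
                               "university"), n, replace = TRUE,
                             prob = c(0.05, 0.3, 0.25, 0.2, 0.2)),
                      levels = c("none", "primary", "technical", "secondary",
                                 "university"))
  energy <- pmax(800, stats::rnorm(n, 2100, 450))
  height <- ifelse(sex == "M", stats::rnorm(n, 176, 7), stats::rnorm(n, 163, 6))
  weight <- bmi * (height / 100)^2
  season <- factor(sample(c("winter", "spring", "summer", "autumn"), n,
                          replace = TRUE),
                   levels = c("winter", "spring", "summer", "autumn"))

  covars <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    center = center, country = country, sex = sex, age = age, bmi = bmi,
    smoking_status = smoking_status, physical_activity = physical_activity,
    alcohol = alcohol, education = education, energy = energy,
    weight = weight, season = season,
    stringsAsFactors = FALSE
  )

  std <- standardized_design(covars)

  # stage 2: person-level and center-level effects, truth
  set.seed(substream_seed(config$seed, 2L))
  re <- correlated_effects(n, config$prob_re_sd, config$amount_re_sd,
                           config$re_correlation)
  ctr_p <- stats::rnorm(config$n_centers, 0, config$center_sd_prob)
  ctr_a <- stats::rnorm(config$n_centers, 0, config$center_sd_amount)
  lp_prob <- linear_predictor(config$consumption_model, std) +
    ctr_p[as.integer(center)] + re[, 1L]
  lp_amt <- linear_predictor(config$amount_model, std) +
    ctr_a[as.integer(center)] + re[, 2L]
  pi_true <- stats::plogis(lp_prob)
  amount_true <- exp(lp_amt)
  t_true <- pi_true * amount_true

  # stage 3: questionnaire
  set.seed(substream_seed(config$seed, 3L))
  qb <- config$q_bias
  # never-consumers as reported on the questionnaire are concentrated among
  # subjects with genuinely low consumption probability
  nc_w <- (1 - pi_true)^3
  nc_prob <- pmin(1, config$q_zero_fraction_target * nc_w / mean(nc_w))
  never_reporter <- stats::rbinom(n, 1L, nc_prob) == 1L
  q_raw <- qb$intercept + qb$slope * t_true +
    stats::rnorm(n, 0, qb$person_sd) + stats::rnorm(n, 0, qb$noise_sd)
  q <- ifelse(never_reporter, 0, pmax(0, q_raw))

  # stage 4: survival
  set.seed(substream_seed(config$seed, 4L))
  log_hr <- config$true_log_hr_per100g * t_true / 100 +
    linear_predictor(config$hazard_confounder_effects, std, intercept = FALSE)
  hazard <- config$baseline_hazard * exp(log_hr)
  event_time <- stats::rexp(n, rate = hazard)
  cr <- config$censoring_rate
  cens_rate <- mean(hazard) * cr / (1 - cr)
  cens_time <- stats::rexp(n, rate = cens_rate)
  admin <- 15
  time <- pmin(event_time, cens_time, admin)
  event <- as.integer(event_time <= pmin(cens_time, admin))
  time <- pmax(time, 1e-6)

  out <- cbind(covars,
               data.frame(Q = q, T = t_true, pi_true = pi_true,
                          amount_true = amount_true,
                          time = time, event = event))
  class(out) <- c("cohort_table", "data.frame")
  validate_cohort_table(out)
  out
}

#' Draw the calibration sub-study with a single reference measurement
#'
#' Samples `n_calib` subjects from the cohort, stratified by center
#' (proportional allocation), and attaches one short-term reference
#' measurement per subject: `R_i = B_i * G_i` with
#' `B_i ~ Bernoulli(pi_i)` (did the subject consume on the recall day) and
#' `G_i` gamma-distributed with mean `A_i` and the configured shape. Hence
#' `E[R_i] = pi_i * A_i = T_i`: the reference is unbiased for true usual
#' intake, the key assumption of regression calibration.
#'
#' @param cohort A `cohort_table` produced by [generate_cohort()] with the
#'   matching `config`.
#' @param config The same [generator_config()] used to generate `cohort`.
#' @return A `data.frame` of class `calibration_table`: the sampled cohort
#'   rows plus a column `R` (g/day, possibly zero).
#' @export
draw_reference <- function(cohort, config) {
  validate_generator_config(config)
  validate_cohort_table(cohort)
  if (config$n_calib > nrow(cohort))
    stop("n_calib exceeds the number of cohort subjects", call. = FALSE)

  set.seed(substream_seed(config$seed, 5L))
  idx <- stratified_sample(cohort$center, config$n_calib)
  sub <- cohort[idx, , drop = FALSE]

  set.seed(substream_seed(config$seed, 6L))
  b <- stats::rbinom(nrow(sub), 1L, sub$pi_true)
  shape <- config$gamma_shape
  g <- stats::rgamma(nrow(sub), shape = shape, scale = sub$amount_true / shape)
  sub$R <- b * g
  rownames(sub) <- NULL
  class(sub) <- c("calibration_table", "cohort_table", "data.frame")
  validate_calibration_table(sub)
  sub
}

#' Validate cohort and calibration tables
#'
#' Checks the schema and invariants: required columns present, no missing
#' values, `Q >= 0`, `T >= 0`, `time > 0`, event binary; for calibration
#' tables additionally `R >= 0` and one row per subject (single-replicate
#' design).
#'
#' @param x A `cohort_table` or `calibration_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort_table <- function(x) {
  need <- c("subject_id", "center", "country", "sex", "age", "bmi",
            "smoking_status", "physical_activity", "alcohol", "education",
            "energy", "weight", "season", "Q", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(x[need]))
    stop("cohort table contains missing values", call. = FALSE)
  if (any(x$Q < 0)) stop("cohort table has Q < 0", call. = FALSE)
  if ("T" %in% names(x) && any(x$T < 0))
    stop("cohort table has T < 0", call. = FALSE)
  if (any(x$time <= 0)) stop("cohort table has time <= 0", call. = FALSE)
  if (!all(x$event %in% c(0L, 1L)))
    stop("cohort table has non-binary event indicator", call. = FALSE)
  invisible(x)
}

#' @rdname validate_cohort_table
#' @export
validate_calibration_table <- function(x) {
  validate_cohort_table(x)
  if (!"R" %in% names(x))
    stop("calibration table is missing column R", call. = FALSE)
  if (anyNA(x$R) || any(x$R < 0))
    stop("calibration table has missing or negative R", call. = FALSE)
  if (anyDuplicated(x$subject_id))
    stop("calibration table has duplicated subjects (single-replicate design)",
         call. = FALSE)
  invisible(x)
}

# Standardized numeric design used by the generative linear predictors.
standardized_design <- function(covars) {
  data.frame(
    age_std = (covars$age - 52.5) / 10,
    bmi_std = (covars$bmi - 26) / 4,
    energy_std = (covars$energy - 2100) / 450,
    alcohol_std = (covars$alcohol - 12) / 11,
    sexM = as.numeric(covars$sex == "M")
  )
}

linear_predictor <- function(coefs, std, intercept = TRUE) {
  lp <- if (intercept && "intercept" %in% names(coefs))
    rep(coefs[["intercept"]], nrow(std)) else rep(0, nrow(std))
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% names(std))
      stop(sprintf("unknown covariate '%s' in generator coefficients; known: %s",
                   nm, paste(names(std), collapse = ", ")), call. = FALSE)
    lp <- lp + coefs[[nm]] * std[[nm]]
  }
  lp
}

# Proportional-allocation stratified sample of row indices by a factor.
stratified_sample <- function(strata, n_total) {
  strata <- droplevels(factor(strata))
  counts <- table(strata)
  alloc <- floor(n_total * counts / sum(counts))
  # distribute the remainder to the largest fractional parts
  frac <- n_total * counts / sum(counts) - alloc
  short <- n_total - sum(alloc)
  if (short > 0) {
    add <- order(frac, decreasing = TRUE)[seq_len(short)]
    alloc[add] <- alloc[add] + 1L
  }
  idx <- unlist(lapply(names(alloc), function(lv) {
    pool <- which(strata == lv)
    sample(pool, min(alloc[[lv]], length(pool)))
  }), use.names = FALSE)
  sort(idx)
}

correlated_effects <- function(n, sd1, sd2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  cbind(sd1 * z1, sd2 * z2)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<%s> %d subjects, %d centers, %d events (%.1f%%)\n",
              class(x)[1], nrow(x), nlevels(droplevels(x$center)),
              sum(x$event), 100 * mean(x$event)))
  if ("R" %in% names(x))
    cat(sprintf("  reference zero fraction: %.1f%%\n", 100 * mean(x$R == 0)))
  cat(sprintf("  Q: mean %.1f g/day, %.1f%% zero\n",
              mean(x$Q), 100 * mean(x$Q == 0)))
  invisible(x)
}
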
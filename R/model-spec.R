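#' Declarative specification of one calibration-model part
#'
#' Describes one part of a calibration model: which part it is (consumption
#' probability, consumed amount, or the one-part linear comparator), how the
#' questionnaire measurement Q is transformed, which covariates enter as
#' main effects, which covariates interact with transformed Q, and whether a
#' quadratic age term is included. The transformed Q is always a main effect
#' and can never be removed; interactions may only reference covariates that
#' are present as main effects.
#'
#' @param part `"probability"`, `"amount"`, or `"one_part"`.
#' @param q_transform `"identity"`, `"sqrt"`, or `"log1p"`
#'   (`log(Q + offset)` with the offset keeping never-consumers, `Q = 0`,
#'   in the model).
#' @param main_effects Character vector of covariate column names.
#' @param interactions Character vector of covariate names whose interaction
#'   with transformed Q is included; must be a subset of `main_effects`.
#' @param quad_age Include an `age^2` term (used in the consumed amount part
#'   of the standard model)?
#' @param log_offset Offset inside the log transform (default 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(part = c("probability", "amount", "one_part"),
                       q_transform = c("identity", "sqrt", "log1p"),
                       main_effects = character(),
                       interactions = character(),
                       quad_age = FALSE,
                       log_offset = 1) {
  part <- match.arg(part)
  q_transform <- match.arg(q_transform)
  bad <- setdiff(interactions, main_effects)
  if (length(bad))
    stop("interactions reference covariates absent from main_effects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (quad_age && !"age" %in% main_effects)
    stop("quad_age requires 'age' among the main effects", call. = FALSE)
  structure(list(part = part, q_transform = q_transform,
                 main_effects = main_effects, interactions = interactions,
                 quad_age = quad_age, log_offset = log_offset),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s part, Q transform %s>\n", x$part, x$q_transform))
  cat("  main effects:", if (length(x$main_effects))
    paste(x$main_effects, collapse = ", ") else "(none)", "\n")
  if (length(x$interactions))
    cat("  Q interactions:", paste(x$interactions, collapse = ", "), "\n")
  if (x$quad_age) cat("  quadratic age term\n")
  invisible(x)
}

q_transform_fun <- function(name, offset = 1) {
  switch(name,
         identity = function(q) q,
         sqrt = function(q) sqrt(q),
         log1p = function(q) log(q + offset),
         stop("unknown Q transform: ", name, call. = FALSE))
}

# Model formula for one part. The transformed Q enters as the column `qt`
# added by prepare_model_frame().
spec_formula <- function(spec, response) {
  terms <- c("qt", spec$main_effects)
  if (spec$quad_age) terms <- c(terms, "I(age^2)")
  if (length(spec$interactions))
    terms <- c(terms, paste0("qt:", spec$interactions))
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

# Adds the transformed-Q column and (for fitting on a calibration table)
# the consumption indicator.
prepare_model_frame <- function(spec, data) {
  out <- as.data.frame(data)
  out$qt <- q_transform_fun(spec$q_transform, spec$log_offset)(out$Q)
  if ("R" %in% names(out)) out$consumed <- as.integer(out$R > 0)
  out
}

#' The standard calibration-model covariate sets
#'
#' Returns the pair of model specifications used as the "standard" two-part
#' calibration model: the eight disease-model confounders (BMI, smoking
#' status, physical activity, lifetime alcohol, education, age, total
#' energy, sex) plus the intake predictors season, center and body weight as
#' main effects; transformed Q; two-way interactions of transformed Q with
#' sex, age, season, BMI and center; and an additional quadratic age term in
#' the consumed amount part only. The "reduced" forms are obtained by
#' running [backward_eliminate()] on each part.
#'
#' @param q_transform_prob,q_transform_amount Q transform per part
#'   (defaults: log for the probability part, sqrt for the amount part, the
#'   forms selected by the AIC exploration for leafy-vegetable-like data).
#' @return A list with elements `probability` and `amount`, each a
#'   [model_spec()].
#' @export
build_standard_specs <- function(q_transform_prob = "log1p",
                                 q_transform_amount = "sqrt") {
  confounders <- c("bmi", "smoking_status", "physical_activity", "alcohol",
                   "education", "age", "energy", "sex")
  intake_predictors <- c("season", "center", "weight")
  mains <- c(confounders, intake_predictors)
  inter <- c("sex", "age", "season", "bmi", "center")
  list(
    probability = model_spec("probability", q_transform_prob,
                             main_effects = mains, interactions = inter),
    amount = model_spec("amount", q_transform_amount,
                        main_effects = mains, interactions = inter,
                        quad_age = TRUE)
  )
}
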
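#' Backward elimination of calibration-model covariates
#'
#' Iteratively refits one part of the calibration model, removing at each
#' step the single least significant removable term by a Wald chi-square
#' test, until every remaining term is significant at level `alpha`
#' (default 0.2, chosen permissively so that no genuinely predictive
#' covariate is excluded). Rules:
#'
#' * the transformed Q main effect is never removable;
#' * a covariate main effect is removable only after every interaction
#'   containing it has been removed (model hierarchy); the quadratic age
#'   term likewise protects the age main effect;
#' * multi-level categorical terms are tested jointly (one Wald chi-square
#'   on all their coefficients).
#'
#' @param calib A `calibration_table`.
#' @param spec A [model_spec()] for the part to reduce.
#' @param alpha Significance level for retention (default 0.2).
#' @return The reduced [model_spec()] (the input spec unchanged when every
#'   term is significant), with an attribute `elimination_path` listing the
#'   removed terms and their p-values in removal order.
#' @export
backward_eliminate <- function(calib, spec, alpha = 0.2) {
  current <- spec
  path <- data.frame(term = character(), p_value = numeric(),
                     stringsAsFactors = FALSE)
  repeat {
    fit <- fit_spec_part(calib, current)
    pv <- term_wald_pvalues(fit)
    cand <- removable_terms(current)
    cand <- cand[cand %in% names(pv)]
    if (!length(cand)) break
    worst <- cand[which.max(pv[cand])]
    if (pv[worst] < alpha) break
    path <- rbind(path, data.frame(term = worst, p_value = unname(pv[worst]),
                                   stringsAsFactors = FALSE))
    current <- drop_term(current, worst)
  }
  attr(current, "elimination_path") <- path
  current
}

# Fits the GLM/OLS for a single spec part on the calibration table.
fit_spec_part <- function(calib, spec) {
  d <- prepare_model_frame(spec, calib)
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  switch(spec$part,
    probability = stats::glm(spec_formula(spec, "consumed"),
                             family = stats::binomial("logit"), data = d,
                             control = ctrl),
    amount = fit_gamma_log(spec_formula(spec, "R"),
                           d[d$R > 0, , drop = FALSE]),
    one_part = stats::lm(spec_formula(spec, "R"), data = d))
}

# Joint Wald chi-square p-value per model term, grouping the coefficients of
# multi-level factors via the model matrix 'assign' attribute.
term_wald_pvalues <- function(fit) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  # dispersion-scaled vcov for gamma GLM comes out of vcov() already
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  ok <- !is.na(b)
  pv <- vapply(seq_along(labels), function(j) {
    idx <- which(asgn == j & ok)
    if (!length(idx)) return(NA_real_)
    bj <- b[idx]
    Vj <- V[idx, idx, drop = FALSE]
    w <- tryCatch(as.numeric(crossprod(bj, solve(Vj, bj))),
                  error = function(e) NA_real_)
    if (is.na(w)) return(NA_real_)
    stats::pchisq(w, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
  names(pv) <- labels
  pv[!is.na(pv)]
}

# Terms currently allowed to leave the model: all interactions and the
# quadratic age term, plus main effects with no remaining dependants.
# Transformed Q is never removable.
removable_terms <- function(spec) {
  out <- character()
  if (length(spec$interactions)) out <- c(out, paste0("qt:", spec$interactions))
  if (spec$quad_age) out <- c(out, "I(age^2)")
  for (v in spec$main_effects) {
    protected <- v %in% spec$interactions || (v == "age" && spec$quad_age)
    if (!protected) out <- c(out, v)
  }
  out
}

drop_term <- function(spec, term) {
  if (startsWith(term, "qt:")) {
    spec$interactions <- setdiff(spec$interactions, sub("^qt:", "", term))
  } else if (term == "I(age^2)") {
    spec$quad_age <- FALSE
  } else {
    spec$main_effects <- setdiff(spec$main_effects, term)
  }
  spec
}
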
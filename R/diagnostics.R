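#' Variance-mean power diagnostic for the consumed amount
#'
#' Chooses a GLM variance family for the positive consumed amounts by the
#' graphical power-variance method: within each group (typically a study
#' center) compute the standard deviation and mean of the positive amounts,
#' then regress log(SD) on log(mean) by ordinary least squares. Under the
#' power-proportional variance function `Var = kappa^2 * mean^lambda`,
#' `log(SD) = log(kappa) + (lambda / 2) * log(mean)`, so `lambda` is
#' estimated as twice the fitted slope: `lambda = 0` means constant
#' variance, `lambda = 1` a Poisson-like variance proportional to the mean,
#' and `lambda = 2` a gamma-like SD proportional to the mean.
#'
#' Zeros must be excluded upstream: the diagnostic concerns consumers only.
#'
#' @param amounts Positive consumed amounts (g/day).
#' @param group Group identifier (e.g. center), same length as `amounts`.
#' @param min_group_n Groups with fewer observations are excluded from the
#'   regression and reported in the result.
#' @return An object of class `variance_mean_result` with the per-group
#'   table, the OLS `slope` and `slope_se`, `lambda_hat = 2 * slope`, and a
#'   `suggested_family` among constant-variance / poisson-like / gamma-like
#'   / other (midpoint bands around the three anchors).
#' @export
variance_mean_slope <- function(amounts, group, min_group_n = 10) {
  if (length(amounts) != length(group))
    stop("amounts and group must have the same length", call. = FALSE)
  if (any(is.na(amounts)) || any(amounts <= 0))
    stop("all amounts must be positive: exclude zero reference measurements upstream",
         call. = FALSE)
  group <- factor(group)
  tab <- data.frame(
    group = levels(group),
    n = as.integer(tapply(amounts, group, length)),
    mean = as.numeric(tapply(amounts, group, mean)),
    sd = as.numeric(tapply(amounts, group, stats::sd)),
    stringsAsFactors = FALSE
  )
  tab$used <- tab$n >= min_group_n & !is.na(tab$sd) & tab$sd > 0
  used <- tab[tab$used, , drop = FALSE]
  if (nrow(used) < 3)
    stop(sprintf("variance-mean diagnostic needs >= 3 groups with n >= %d; got %d",
                 min_group_n, nrow(used)), call. = FALSE)
  fit <- stats::lm(log(sd) ~ log(mean), data = used)
  slope <- unname(stats::coef(fit)[2])
  # a perfect fit (zero residual variance) is a legitimate outcome here
  slope_se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  lambda_hat <- 2 * slope
  fam <- if (lambda_hat >= -0.5 && lambda_hat < 0.5) "constant-variance"
    else if (lambda_hat < 1.5) "poisson-like"
    else if (lambda_hat <= 2.5) "gamma-like"
    else "other"
  structure(list(groups = tab, slope = slope, slope_se = slope_se,
                 lambda_hat = lambda_hat, suggested_family = fam,
                 n_excluded = sum(!tab$used), min_group_n = min_group_n),
            class = "variance_mean_result")
}

#' @export
print.variance_mean_result <- function(x, ...) {
  cat(sprintf("Variance-mean diagnostic: slope %.3f (SE %.3f), lambda-hat %.3f -> %s\n",
              x$slope, x$slope_se, x$lambda_hat, x$suggested_family))
  cat(sprintf("  %d groups used, %d excluded (n < %d)\n",
              sum(x$groups$used), x$n_excluded, x$min_group_n))
  invisible(x)
}

#' Empirical logit curve of consumption probability against questionnaire intake
#'
#' Bins the questionnaire measurement Q into a first category of exact zeros
#' (never-consumers as reported) followed by half-open intervals of width
#' `bin_width` g/day, and computes in each category the empirical logit of
#' consumption as reported on the reference instrument:
#' `ln((y + 0.5) / (n - y + 0.5))`, where `y` counts subjects with a
#' positive reference measurement and `n` the subjects in the category. The
#' +0.5 continuity correction keeps every value finite at `y = 0` and
#' `y = n` and minimises the bias of the log-odds estimate. The curve is the
#' standard visual check for the parametric form of Q in the consumption
#' probability model.
#'
#' @param r_indicator 0/1 per subject: consumption reported on the reference
#'   measurement (`R > 0`).
#' @param q Questionnaire intake, g/day, `>= 0`.
#' @param bin_width Width of the Q categories in g/day (default 10).
#' @return An object of class `empirical_logit_curve`: a data.frame with
#'   one row per nonempty category (`category`, `q_mean`, `n`, `y`,
#'   `logit`), plus attributes `bin_width` and `degenerate` (TRUE with a
#'   warning when all Q fall in one category).
#' @export
empirical_logit_curve <- function(r_indicator, q, bin_width = 10) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (any(q < 0)) stop("Q must be >= 0", call. = FALSE)
  if (length(r_indicator) != length(q))
    stop("r_indicator and q must have the same length", call. = FALSE)
  r_indicator <- as.integer(r_indicator > 0)
  # category 0 is exactly {Q = 0}; k >= 1 is [k*w, (k+1)*w) shifted so that
  # positive values below bin_width land in their own bin
  k <- ifelse(q == 0, 0L, floor(q / bin_width) + 1L)
  ks <- sort(unique(k))
  rows <- lapply(ks, function(ki) {
    in_cat <- k == ki
    n_i <- sum(in_cat)
    y_i <- sum(r_indicator[in_cat])
    lab <- if (ki == 0L) "Q=0"
      else sprintf("[%g,%g)", (ki - 1L) * bin_width, ki * bin_width)
    data.frame(category = lab, q_mean = mean(q[in_cat]), n = n_i, y = y_i,
               logit = log((y_i + 0.5) / (n_i - y_i + 0.5)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  degenerate <- nrow(out) == 1L
  if (degenerate)
    warning("all Q values fall in a single category; empirical logit curve has length 1",
            call. = FALSE)
  structure(out, bin_width = bin_width, degenerate = degenerate,
            class = c("empirical_logit_curve", "data.frame"))
}

#' Empirical logit of a single binned count
#'
#' The continuity-corrected logit `ln((y + 0.5) / (n - y + 0.5))` used by
#' [empirical_logit_curve()]; exported because it is useful on its own for
#' pre-binned data.
#'
#' @param y Number of successes in the bin.
#' @param n Bin size.
#' @return Finite logit value(s).
#' @export
empirical_logit <- function(y, n) {
  if (any(y < 0) || any(y > n)) stop("need 0 <= y <= n", call. = FALSE)
  log((y + 0.5) / (n - y + 0.5))
}

#' Select the parametric transform of Q for one calibration-model part
#'
#' Fits the part-appropriate GLM (binomial with logit link on the
#' consumption indicator for `part = "probability"`; gamma with log link on
#' the positive amounts for `part = "amount"`) once per candidate transform
#' of Q -- identity, square root, and `log(Q + offset)` -- holding the
#' adjustment covariates fixed, and returns the AICs and the winner. Ties
#' (AIC difference below `tie_tol`) are broken toward the simpler transform
#' in the order identity < sqrt < log. Optionally attaches a
#' penalized-regression-spline partial prediction of the smoothed Q term
#' (smoothing parameter by generalized cross-validation) for visual
#' confirmation of the chosen form.
#'
#' @param part `"probability"` or `"amount"`.
#' @param calib A `calibration_table`.
#' @param adjust_covariates Character vector of covariate column names held
#'   fixed in every candidate model (may be empty).
#' @param log_offset Offset used inside the log transform so that `Q = 0`
#'   (never-consumers) stays in the model; default 1 (i.e. `log1p`).
#' @param spline Also fit the spline partial-prediction table?
#' @param tie_tol AIC differences below this count as ties.
#' @return An object of class `transform_selection` with per-candidate AICs,
#'   the chosen transform, convergence flags, and optionally a
#'   `spline_partial` data.frame (grid of Q and smoothed linear-predictor
#'   contribution).
#' @export
select_transform <- function(part = c("probability", "amount"), calib,
                             adjust_covariates = character(),
                             log_offset = 1, spline = FALSE, tie_tol = 1e-8) {
  part <- match.arg(part)
  if (nrow(calib) == 0) stop("calibration table is empty", call. = FALSE)
  if (!"R" %in% names(calib)) stop("calibration table must contain R", call. = FALSE)

  dat <- as.data.frame(calib)
  dat$.consumed <- as.integer(dat$R > 0)
  if (part == "amount") {
    dat <- dat[dat$R > 0, , drop = FALSE]
    if (nrow(dat) == 0)
      stop("no consumers (R > 0) available for the amount part", call. = FALSE)
  }

  transforms <- list(identity = function(q) q,
                     sqrt = function(q) sqrt(q),
                     log = function(q) log(q + log_offset))
  rhs_fixed <- if (length(adjust_covariates))
    paste(adjust_covariates, collapse = " + ") else NULL

  fit_one <- function(tname) {
    dat$.qt <- transforms[[tname]](dat$Q)
    rhs <- paste(c(".qt", rhs_fixed), collapse = " + ")
    fml <- stats::as.formula(paste(
      if (part == "probability") ".consumed ~" else "R ~", rhs))
    fit <- tryCatch(
      if (part == "probability")
        stats::glm(fml, family = stats::binomial("logit"), data = dat,
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
      else fit_gamma_log(fml, dat),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(list(aic = NA_real_, ok = FALSE))
    list(aic = stats::AIC(fit), ok = TRUE)
  }
  res <- lapply(names(transforms), fit_one)
  aics <- vapply(res, `[[`, numeric(1), "aic")
  ok <- vapply(res, `[[`, logical(1), "ok")
  names(aics) <- names(ok) <- names(transforms)
  if (!any(ok)) stop("no candidate transform converged", call. = FALSE)

  # simplicity order identity < sqrt < log; ties go to the simpler one
  usable <- which(ok)
  best <- usable[1]
  for (i in usable[-1]) if (aics[i] < aics[best] - tie_tol) best <- i
  chosen <- names(transforms)[best]

  spline_partial <- NULL
  if (spline) {
    dat$.qt <- dat$Q
    rhs <- paste(c("s(.qt)", rhs_fixed), collapse = " + ")
    fml <- stats::as.formula(paste(
      if (part == "probability") ".consumed ~" else "R ~", rhs))
    fam <- if (part == "probability") stats::binomial("logit")
      else stats::Gamma("log")
    gfit <- mgcv::gam(fml, family = fam, data = dat, method = "GCV.Cp")
    grid <- data.frame(.qt = seq(min(dat$Q), max(dat$Q), length.out = 100))
    for (cv in adjust_covariates) {
      col <- dat[[cv]]
      grid[[cv]] <- if (is.numeric(col)) mean(col) else
        factor(names(which.max(table(col))), levels = levels(factor(col)))
    }
    pp <- stats::predict(gfit, newdata = grid, type = "terms")
    sm_col <- grep("\\.qt", colnames(pp))
    spline_partial <- data.frame(Q = grid$.qt, partial = pp[, sm_col[1]])
  }

  structure(list(part = part, aic = aics, converged = ok, chosen = chosen,
                 log_offset = log_offset, spline_partial = spline_partial),
            class = "transform_selection")
}

#' @export
print.transform_selection <- function(x, ...) {
  cat(sprintf("Transform selection (%s part): chose '%s'\n", x$part, x$chosen))
  for (nm in names(x$aic))
    cat(sprintf("  %-8s AIC %s%s\n", nm,
                ifelse(is.na(x$aic[nm]), "did not converge",
                       sprintf("%.2f", x$aic[nm])),
                ifelse(nm == x$chosen, "  <- chosen", "")))
  invisible(x)
}
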
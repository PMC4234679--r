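#' Read the main-study and calibration tables from CSV
#'
#' Reads and validates the two delimited-text inputs of the workflow: the
#' main-study table (one row per subject) and the calibration sub-study
#' table (a subset of subjects with one reference measurement `R` each).
#' Categorical levels are harmonised across the two files so a model fitted
#' on the calibration table predicts cleanly on the cohort.
#'
#' @param cohort_path,calib_path CSV file paths (RFC 4180, UTF-8, "."
#'   decimal separator) with the documented header schema (see
#'   [validate_cohort_table()]).
#' @return A list with elements `cohort` (a `cohort_table`) and `calib` (a
#'   `calibration_table`).
#' @export
read_cohort_tables <- function(cohort_path, calib_path) {
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  calib <- utils::read.csv(calib_path, stringsAsFactors = FALSE)
  if (!"R" %in% names(calib))
    stop("calibration file is missing the reference column R", call. = FALSE)
  missing_ids <- setdiff(calib$subject_id, cohort$subject_id)
  if (length(missing_ids))
    stop("calibration subjects absent from the cohort: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  factor_cols <- c("center", "country", "sex", "smoking_status",
                   "physical_activity", "education", "season")
  for (cl in factor_cols) {
    levs <- sort(unique(c(cohort[[cl]], calib[[cl]])))
    cohort[[cl]] <- factor(cohort[[cl]], levels = levs)
    calib[[cl]] <- factor(calib[[cl]], levels = levs)
  }
  class(cohort) <- c("cohort_table", "data.frame")
  class(calib) <- c("calibration_table", "cohort_table", "data.frame")
  validate_cohort_table(cohort)
  validate_calibration_table(calib)
  list(cohort = cohort, calib = calib)
}

#' Write cohort / calibration tables as CSV
#'
#' @param x A `cohort_table` or `calibration_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' Either a generator preset (synthetic mode) or a pair of input CSV paths
#' (data mode) -- exactly one of the two -- plus the comparator list,
#' bootstrap size and seed.
#'
#' @param generator A [generator_config()], or `NULL` in data mode.
#' @param cohort_path,calib_path Input CSVs in data mode, `NULL` otherwise.
#' @param comparators Subset of `c("naive", "one_part",
#'   "two_part_untransformed", "two_part_transformed")`.
#' @param specs `"standard"` for [build_standard_specs()], or a list with
#'   elements `probability` and `amount` ([model_spec()]s).
#' @param reduce Also fit the reduced (backward-eliminated) forms?
#' @param alpha Elimination level (default 0.2).
#' @param bootstrap_m Bootstrap replicates per calibrated comparator
#'   (0 disables the bootstrap).
#' @param confounders Confounders for the disease model; default the eight
#'   standard ones.
#' @param strata Cox stratification (default center and sex).
#' @param seed Master seed for every source of randomness.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = NULL,
                       cohort_path = NULL, calib_path = NULL,
                       comparators = c("naive", "one_part",
                                       "two_part_untransformed",
                                       "two_part_transformed"),
                       specs = "standard",
                       reduce = TRUE,
                       alpha = 0.2,
                       bootstrap_m = 25,
                       confounders = c("bmi", "smoking_status",
                                       "physical_activity", "alcohol",
                                       "education", "age", "energy"),
                       strata = c("center", "sex"),
                       seed = 1L,
                       output_dir = NULL) {
  synthetic <- !is.null(generator)
  from_files <- !is.null(cohort_path) || !is.null(calib_path)
  if (synthetic == from_files)
    stop("provide exactly one of a generator config or input file paths",
         call. = FALSE)
  if (from_files && (is.null(cohort_path) || is.null(calib_path)))
    stop("data mode needs both cohort_path and calib_path", call. = FALSE)
  known <- c("naive", "one_part", "two_part_untransformed",
             "two_part_transformed")
  bad <- setdiff(comparators, known)
  if (length(bad))
    stop("unknown comparators: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(generator = generator, cohort_path = cohort_path,
                 calib_path = calib_path, comparators = comparators,
                 specs = specs, reduce = reduce, alpha = alpha,
                 bootstrap_m = bootstrap_m, confounders = confounders,
                 strata = strata, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full calibration workflow
#'
#' Orchestrates simulate/read, calibrate, associate and combine for every
#' requested comparator, in the standard and (optionally) reduced covariate
#' forms, and assembles a comparison report with one row per comparator and
#' form: the log hazard ratio per 100 g/day, the within-only SE, the
#' bootstrap-combined SE, their ratio, and the extreme-prediction count.
#'
#' @param config A [run_config()].
#' @return An object of class `comparison_report`: a data.frame of results
#'   with attributes `seed`, `n_main`, `n_calib`, and (in synthetic mode)
#'   `true_log_hr_per100g`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config",
                                            call. = FALSE)
  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator)
    calib <- draw_reference(cohort, config$generator)
  } else {
    tabs <- read_cohort_tables(config$cohort_path, config$calib_path)
    cohort <- tabs$cohort
    calib <- tabs$calib
  }

  specs <- if (identical(config$specs, "standard")) build_standard_specs()
    else config$specs
  forms <- if (config$reduce) c("standard", "reduced") else "standard"

  rows <- list()
  add_row <- function(comparator, form, est, se_within, se_comb, n_extreme) {
    rows[[length(rows) + 1]] <<- data.frame(
      comparator = comparator, form = form, log_hr_per_100g = est,
      se_within = se_within, se_combined = se_comb,
      se_ratio = if (is.na(se_comb)) NA_real_ else se_comb / se_within,
      n_extreme = n_extreme, stringsAsFactors = FALSE)
  }

  if ("naive" %in% config$comparators) {
    nv <- naive_association(cohort, config$confounders, config$strata)
    add_row("naive", "standard", nv$log_hr_per_100g, nv$se, NA_real_, 0L)
    if (config$reduce)
      add_row("naive", "reduced", nv$log_hr_per_100g, nv$se, NA_real_, 0L)
  }

  run_two_part <- function(comparator, s1, s2, form, boot_seed) {
    fit <- fit_two_part(calib, s1, s2)
    pred <- predict_usual_intake(fit, cohort)
    cox <- fit_cox(cohort, pred$predicted, config$confounders,
                   config$strata, exclude = pred$extreme)
    se_comb <- NA_real_
    if (config$bootstrap_m >= 2) {
      run <- bootstrap_calibrated_association(
        calib, cohort, s1, s2, m = config$bootstrap_m, seed = boot_seed,
        confounders = config$confounders, strata = config$strata)
      se_comb <- rubin_combine(run)$total_se
    }
    add_row(comparator, form, cox$log_hr_per_100g, cox$se, se_comb,
            attr(pred, "n_flagged"))
  }

  reduce_pair <- function(s1, s2) {
    list(probability = backward_eliminate(calib, s1, config$alpha),
         amount = backward_eliminate(calib, s2, config$alpha))
  }

  if ("two_part_transformed" %in% config$comparators) {
    run_two_part("two_part_transformed", specs$probability, specs$amount,
                 "standard", config$seed + 11L)
    if (config$reduce) {
      red <- reduce_pair(specs$probability, specs$amount)
      run_two_part("two_part_transformed", red$probability, red$amount,
                   "reduced", config$seed + 12L)
    }
  }

  if ("two_part_untransformed" %in% config$comparators) {
    u1 <- specs$probability; u1$q_transform <- "identity"
    u2 <- specs$amount; u2$q_transform <- "identity"
    run_two_part("two_part_untransformed", u1, u2, "standard",
                 config$seed + 21L)
    if (config$reduce) {
      red <- reduce_pair(u1, u2)
      run_two_part("two_part_untransformed", red$probability, red$amount,
                   "reduced", config$seed + 22L)
    }
  }

  if ("one_part" %in% config$comparators) {
    sp <- model_spec("one_part", "identity",
                     main_effects = specs$probability$main_effects,
                     interactions = specs$probability$interactions)
    run_one_part <- function(s, form) {
      fit <- fit_one_part(calib, s)
      pred <- suppressWarnings(predict_one_part(fit, cohort))
      cox <- fit_cox(cohort, pred$predicted, config$confounders,
                     config$strata, exclude = pred$extreme)
      add_row("one_part", form, cox$log_hr_per_100g, cox$se, NA_real_,
              attr(pred, "n_flagged"))
    }
    run_one_part(sp, "standard")
    if (config$reduce)
      run_one_part(backward_eliminate(calib, sp, config$alpha), "reduced")
  }

  report <- do.call(rbind, rows)
  attr(report, "seed") <- config$seed
  attr(report, "n_main") <- nrow(cohort)
  attr(report, "n_calib") <- nrow(calib)
  if (!is.null(config$generator))
    attr(report, "true_log_hr_per100g") <- config$generator$true_log_hr_per100g
  class(report) <- c("comparison_report", "data.frame")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(config$output_dir, "comparison_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_main = nrow(cohort), n_calib = nrow(calib),
           comparators = config$comparators),
      file.path(config$output_dir, "manifest.json"), auto_unbox = TRUE)
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report (n_main = %d, n_calib = %d, seed = %d)\n",
              attr(x, "n_main"), attr(x, "n_calib"), attr(x, "seed")))
  if (!is.null(attr(x, "true_log_hr_per100g")))
    cat(sprintf("  true log HR per 100 g/day: %.3f\n",
                attr(x, "true_log_hr_per100g")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
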
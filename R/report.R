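#' End-to-end threshold analysis report
#'
#' Runs the full analysis suite on a cohort: alpha/beta sweeps over the
#' whole cohort and the age subgroups (< 70 vs >= 70 years), joint selection
#' of the best-supported alpha/beta ratio (highest Youden's J in both the
#' overall cohort and the under-70 subgroup when available), Kaplan-Meier
#' cumulative incidence stratified at the selected BED threshold with a
#' log-rank test, univariate Cox models per covariate and a multivariate
#' Cox model, variance inflation factors for the multivariate design,
#' a one-way ANOVA of the selected BED across outcome groups, and ROC
#' cutoffs for PTV and age as continuous predictors.
#'
#' A subgroup whose outcome column is single-class gets `NULL` sweep results
#' and a note; the run continues. A cohort with no events (or no
#' non-events) errors before any stage runs.
#'
#' @param cohort Cohort tibble in the schema of [cohort_columns()].
#' @param grid,fractions Passed to [sweep_alpha_beta()].
#' @param age_cutoff Age boundary (years) for the subgroup split.
#' @param covariates Covariates for the Cox models; defaults to the
#'   registry covariate set (BED at alpha/beta = 3 is added as `bed_ab3`).
#' @param ties Tie correction for [cox_fit()].
#'
#' @return A list of class `ptbe_report`: `sweep_overall`, `sweep_under`,
#'   `sweep_over` (sweep tibbles or `NULL`), `subgroup_notes`,
#'   `selected_alpha_beta`, `bed_threshold_gy`, `bed_threshold_under_gy`,
#'   `km`, `logrank`, `cox_univariate` (tibble), `cox_multivariate`
#'   (`cox_fit`), `vif`, `anova_bed`, `ptv_cutoff`, `age_cutoff_roc`,
#'   `meta`.
#' @export
run_report <- function(cohort, grid = 2:20, fractions = c(1, 3, 5, 8, 10, 15, 20),
                       age_cutoff = 70,
                       covariates = c("sex", "age_years", "bmi", "ptv_cc",
                                      "bed_ab3", "n_fractions", "hypertension",
                                      "diabetes"),
                       ties = "breslow") {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop_empty("`cohort` has no rows.")
  labels <- as_binary_label(cohort$ptbe_event, "ptbe_event")
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop_degenerate_outcome("Cohort outcome is single-class; nothing to analyse.")
  }
  cohort <- dplyr::mutate(
    cohort,
    bed_ab3 = compute_bed(.data$n_fractions, .data$dose_per_fraction_gy, 3)
  )

  notes <- character()
  try_sweep <- function(subset, label) {
    if (nrow(subset) == 0) {
      notes <<- c(notes, sprintf("%s: empty subgroup; sweep unavailable.", label))
      return(NULL)
    }
    tryCatch(
      sweep_alpha_beta(subset, grid = grid, fractions = fractions),
      bedsweep_degenerate_labels = function(cnd) {
        notes <<- c(notes, sprintf("%s: single outcome class; sweep unavailable.", label))
        NULL
      }
    )
  }
  sweep_overall <- sweep_alpha_beta(cohort, grid = grid, fractions = fractions)
  under <- cohort[cohort$age_years < age_cutoff, ]
  over <- cohort[cohort$age_years >= age_cutoff, ]
  sweep_under <- try_sweep(under, sprintf("age < %s", age_cutoff))
  sweep_over <- try_sweep(over, sprintf("age >= %s", age_cutoff))

  selected <- select_best_alpha_beta(sweep_overall, sweep_under)
  thr <- sweep_overall$optimal_bed_gy[sweep_overall$alpha_beta == selected]
  thr_under <- if (!is.null(sweep_under)) {
    sweep_under$optimal_bed_gy[sweep_under$alpha_beta == selected]
  } else {
    NA_real_
  }

  cohort <- dplyr::mutate(
    cohort,
    bed_selected = compute_bed(.data$n_fractions, .data$dose_per_fraction_gy, selected),
    bed_stratum = ifelse(.data$bed_selected >= thr, "high_bed", "low_bed")
  )
  km <- km_estimate(cohort, by = bed_stratum)
  logrank <- if (length(unique(cohort$bed_stratum)) == 2) {
    tryCatch(logrank_test(cohort, bed_stratum),
      bedsweep_undefined_test = function(cnd) NULL
    )
  } else {
    NULL
  }

  cox_uni <- purrr::map_dfr(covariates, function(cv) {
    fit <- cox_fit(cohort, cv, ties = ties)
    out <- tidy(fit, exponentiate = TRUE)
    out$covariate <- cv
    out$converged <- fit$converged
    out
  })
  cox_multi <- cox_fit(cohort, covariates, ties = ties)

  design <- model.matrix(reformulate(covariates), data = cohort)
  design <- design[, colnames(design) != "(Intercept)", drop = FALSE]
  vif_tbl <- vif(design)

  anova_bed <- one_way_anova(cohort, bed_selected, ptbe_event)

  roc_cut <- function(col) {
    curve <- empirical_roc(cohort[[col]], labels)
    opt <- corner_optimal(curve)
    dplyr::mutate(opt,
      auc = roc_auc(curve),
      p_value = auc_pvalue(cohort[[col]], labels),
      predictor = col
    )
  }

  structure(
    list(
      sweep_overall = sweep_overall, sweep_under = sweep_under,
      sweep_over = sweep_over, subgroup_notes = notes,
      selected_alpha_beta = selected,
      bed_threshold_gy = thr, bed_threshold_under_gy = thr_under,
      km = km, logrank = logrank,
      cox_univariate = cox_uni, cox_multivariate = cox_multi,
      vif = vif_tbl, anova_bed = anova_bed,
      ptv_cutoff = roc_cut("ptv_cc"), age_cutoff_roc = roc_cut("age_years"),
      meta = list(
        n_tumors = nrow(cohort), n_events = sum(labels),
        grid = alpha_beta_grid(grid), fractions = fractions,
        age_cutoff = age_cutoff, covariates = covariates, ties = ties,
        cohort_hash = rlang::hash(cohort[, cohort_columns()[cohort_columns() %in% names(cohort)]]),
        package_version = as.character(utils::packageVersion("bedsweep"))
      )
    ),
    class = "ptbe_report"
  )
}

#' @export
print.ptbe_report <- function(x, ...) {
  cat("PTBE threshold analysis report\n")
  cat(sprintf(
    "  cohort: %d tumors, %d PTBE events (%.1f%%)\n",
    x$meta$n_tumors, x$meta$n_events, 100 * x$meta$n_events / x$meta$n_tumors
  ))
  cat(sprintf(
    "  selected alpha/beta: %g Gy; optimal BED cutoff: %.3f Gy (overall)",
    x$selected_alpha_beta, x$bed_threshold_gy
  ))
  if (!is.na(x$bed_threshold_under_gy)) {
    cat(sprintf(", %.3f Gy (age < %s)", x$bed_threshold_under_gy, x$meta$age_cutoff))
  }
  cat("\n")
  sel <- x$sweep_overall[x$sweep_overall$alpha_beta == x$selected_alpha_beta, ]
  cat(sprintf(
    "  at the cutoff: AUC %.3f (p = %.3g), sens %.3f, spec %.3f, Youden J %.3f\n",
    sel$auc, sel$p_value, sel$sensitivity, sel$specificity, sel$youden_j
  ))
  if (!is.null(x$logrank)) {
    cat(sprintf(
      "  log-rank (BED >= cutoff vs below): chi-sq %.3f, p = %.3g\n",
      x$logrank$statistic, x$logrank$p_value
    ))
  }
  for (note in x$subgroup_notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Serialise a report to disk
#'
#' Writes the sweep tables and Kaplan-Meier curves as TSV, and the model
#' fits plus scalar results as JSON, under `out_dir`. Output is a pure
#' function of the report object, so re-running the pipeline on identical
#' inputs reproduces the files byte for byte.
#'
#' @param report A `ptbe_report` from [run_report()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "ptbe_report")) stop_invalid("`report` must be a `ptbe_report`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(out_dir, name))
  }
  tsv(report$sweep_overall, "sweep_overall.tsv")
  tsv(report$sweep_under, "sweep_age_under.tsv")
  tsv(report$sweep_over, "sweep_age_over.tsv")
  tsv(report$km, "km_by_bed_stratum.tsv")
  tsv(report$cox_univariate, "cox_univariate.tsv")
  tsv(report$vif, "vif.tsv")
  fits <- list(
    selected_alpha_beta = report$selected_alpha_beta,
    bed_threshold_gy = report$bed_threshold_gy,
    bed_threshold_under_gy = report$bed_threshold_under_gy,
    logrank = report$logrank,
    cox_multivariate = list(
      coefficients = report$cox_multivariate$coefficients,
      loglik = report$cox_multivariate$loglik,
      converged = report$cox_multivariate$converged
    ),
    anova_bed = report$anova_bed,
    ptv_cutoff = report$ptv_cutoff,
    age_cutoff_roc = report$age_cutoff_roc,
    subgroup_notes = report$subgroup_notes,
    meta = report$meta
  )
  jsonlite::write_json(
    fits, file.path(out_dir, "fits.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(out_dir)
}
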
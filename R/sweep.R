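#' Alpha/beta sweep: ROC-optimal BED cutoffs across a grid of ratios
#'
#' For every alpha/beta ratio in `grid`, recomputes cohort BED values,
#' constructs the empirical ROC of BED against the PTBE outcome, and records
#' the AUC, its two-sided p-value, the corner-distance optimal BED cutoff
#' with its sensitivity, specificity and Youden's J, and — for each requested
#' fractionation scheme — the physical dose per fraction isoeffective to the
#' optimal cutoff at that ratio.
#'
#' @param cohort Data frame in the cohort schema (needs `n_fractions`,
#'   `dose_per_fraction_gy`, and the outcome column).
#' @param grid Alpha/beta ratios (Gy); default the integers 2-20.
#' @param fractions Fraction numbers for the isoeffective dose columns;
#'   default `c(1, 3, 5, 8, 10, 15, 20)`.
#' @param outcome Name of the binary outcome column (default `"ptbe_event"`).
#'
#' @return A tibble of class `ab_sweep`, one row per ratio, with columns
#'   `alpha_beta`, `auc`, `p_value`, `optimal_bed_gy`, `sensitivity`,
#'   `specificity`, `youden_j`, and one `dose_fx_<n>` column per requested
#'   scheme (dose per fraction, Gy).
#' @seealso [select_best_alpha_beta()], [autoplot.ab_sweep()]
#' @export
sweep_alpha_beta <- function(cohort, grid = 2:20,
                             fractions = c(1, 3, 5, 8, 10, 15, 20),
                             outcome = "ptbe_event") {
  grid <- alpha_beta_grid(grid)
  check_count(fractions, "fractions")
  if (!outcome %in% names(cohort)) {
    stop_invalid(sprintf("`cohort` has no outcome column `%s`.", outcome))
  }
  labels <- as_binary_label(cohort[[outcome]], outcome)
  if (sum(labels) < 1 || sum(!labels) < 1) {
    stop_degenerate_labels("Cohort must contain both PTBE+ and PTBE- tumors.")
  }
  bm <- bed_matrix(cohort, grid)

  rows <- purrr::map(seq_along(grid), function(j) {
    scores <- bm[, j]
    curve <- empirical_roc(scores, labels)
    opt <- corner_optimal(curve)
    doses <- isoeffective_dose_per_fraction(opt$threshold, fractions, grid[j])
    out <- tibble::tibble(
      alpha_beta = grid[j],
      auc = roc_auc(curve),
      p_value = auc_pvalue(scores, labels),
      optimal_bed_gy = opt$threshold,
      sensitivity = opt$sensitivity,
      specificity = opt$specificity,
      youden_j = opt$youden_j
    )
    out[paste0("dose_fx_", fractions)] <- as.list(doses)
    out
  })
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("ab_sweep", class(res)))
}

#' Select the best-supported alpha/beta ratio from a sweep
#'
#' Default rule: the ratio maximising Youden's J, ties resolved toward the
#' smallest ratio. When a subgroup sweep is supplied, the joint rule is used:
#' candidate ratios must maximise J in *both* tables (intersection of the two
#' argmax sets) before tie-breaking; if the intersection is empty the overall
#' table alone decides.
#'
#' @param sweep An `ab_sweep` tibble (the overall cohort).
#' @param subgroup_sweep Optional second `ab_sweep` (e.g. the under-70
#'   subgroup) for the joint criterion.
#' @return The selected alpha/beta ratio (Gy, scalar).
#' @export
select_best_alpha_beta <- function(sweep, subgroup_sweep = NULL) {
  if (!is.data.frame(sweep) || nrow(sweep) == 0) {
    stop_empty("`sweep` must be a non-empty sweep table.")
  }
  argmax <- function(tbl) tbl$alpha_beta[tbl$youden_j >= max(tbl$youden_j) - 1e-12]
  cand <- argmax(sweep)
  if (!is.null(subgroup_sweep) && nrow(subgroup_sweep) > 0) {
    joint <- intersect(cand, argmax(subgroup_sweep))
    if (length(joint) > 0) cand <- joint
  }
  min(cand)
}
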
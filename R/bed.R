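#' Biologically effective dose under the linear-quadratic model
#'
#' The biologically effective dose (BED) of a fractionation scheme delivering
#' `n_fractions` fractions of `dose_per_fraction` Gy each, for a tissue with
#' linear-quadratic fractionation-sensitivity ratio `alpha_beta` (Gy), is
#'
#' \deqn{\mathrm{BED} = n d \left(1 + \frac{d}{\alpha/\beta}\right)}
#'
#' BED puts heterogeneous schemes (single-fraction radiosurgery through
#' conventionally fractionated courses) on a common biological scale: it is
#' strictly increasing in both `n_fractions` and `dose_per_fraction` and
#' strictly decreasing in `alpha_beta`, approaching the physical total dose
#' \eqn{n d} as \eqn{\alpha/\beta \to \infty}.
#'
#' All three arguments are vectorised and recycled against each other.
#'
#' @param n_fractions Number of fractions (positive whole number).
#' @param dose_per_fraction Dose per fraction in Gy (strictly positive).
#' @param alpha_beta Alpha/beta ratio in Gy (strictly positive).
#'
#' @return BED in Gy, a numeric vector.
#' @seealso [isoeffective_dose_per_fraction()] for the inverse mapping,
#'   [bed_matrix()] to tabulate a cohort over a grid of ratios.
#' @examples
#' compute_bed(1, 10, 10)            # d = alpha/beta doubles the dose: 20 Gy
#' compute_bed(5, 5.75, 14)          # five-fraction scheme near 40.6 Gy BED
#' @export
compute_bed <- function(n_fractions, dose_per_fraction, alpha_beta) {
  check_count(n_fractions, "n_fractions")
  check_positive(dose_per_fraction, "dose_per_fraction")
  check_positive(alpha_beta, "alpha_beta")
  n_fractions * dose_per_fraction * (1 + dose_per_fraction / alpha_beta)
}

#' Isoeffective dose per fraction for a BED target
#'
#' Closed-form inversion of the linear-quadratic BED: the unique positive dose
#' per fraction `d` with `compute_bed(n_fractions, d, alpha_beta) ==
#' target_bed`, i.e. the positive root of
#' \eqn{d^2 + (\alpha/\beta)\,d - (\alpha/\beta)\,\mathrm{BED}/n = 0}:
#'
#' \deqn{d = \frac{-\alpha/\beta + \sqrt{(\alpha/\beta)^2 +
#'   4\,(\alpha/\beta)\,\mathrm{BED}/n}}{2}}
#'
#' This is how a BED threshold is translated back into prescribable physical
#' doses for common fractionation schemes. Arguments are vectorised.
#'
#' @param target_bed Target BED in Gy (strictly positive).
#' @param n_fractions Number of fractions (positive whole number).
#' @param alpha_beta Alpha/beta ratio in Gy (strictly positive).
#'
#' @return Dose per fraction in Gy satisfying the BED round-trip to
#'   numerical precision.
#' @examples
#' isoeffective_dose_per_fraction(40.595, 1, 14)   # ~17.85 Gy single fraction
#' isoeffective_dose_per_fraction(40.595, 5, 14)   # ~5.75 Gy x 5
#' @export
isoeffective_dose_per_fraction <- function(target_bed, n_fractions, alpha_beta) {
  check_positive(target_bed, "target_bed")
  check_count(n_fractions, "n_fractions")
  check_positive(alpha_beta, "alpha_beta")
  (-alpha_beta + sqrt(alpha_beta^2 + 4 * alpha_beta * target_bed / n_fractions)) / 2
}

#' Validate an alpha/beta grid
#'
#' @param values Strictly increasing vector of positive alpha/beta ratios in
#'   Gy. Defaults to the integers 2 through 20.
#' @return The validated numeric vector.
#' @export
alpha_beta_grid <- function(values = 2:20) {
  check_positive(values, "values")
  if (length(values) > 1 && any(diff(values) <= 0)) {
    stop_invalid("`values` must be strictly increasing.")
  }
  as.numeric(values)
}

#' BED matrix of a cohort over an alpha/beta grid
#'
#' Tabulates `compute_bed()` for every tumor in a cohort against every ratio
#' in an alpha/beta grid. Row `i`, column `j` holds the BED of tumor `i`'s
#' fractionation scheme evaluated at ratio `grid[j]`; rows are strictly
#' decreasing along the grid since dose per fraction is positive.
#'
#' @param cohort Data frame with columns `n_fractions` and
#'   `dose_per_fraction_gy` (the cohort CSV schema; see [read_cohort()]).
#' @param grid Alpha/beta ratios, validated by [alpha_beta_grid()].
#'
#' @return Numeric matrix, tumors by ratios, with the grid values as column
#'   names (and `tumor_id` as row names when present).
#' @examples
#' cohort <- tibble::tibble(n_fractions = c(1, 5), dose_per_fraction_gy = c(18, 5.5))
#' bed_matrix(cohort, grid = c(3, 10, 14))
#' @export
bed_matrix <- function(cohort, grid = 2:20) {
  if (!is.data.frame(cohort)) stop_invalid("`cohort` must be a data frame.")
  if (nrow(cohort) == 0) stop_empty("`cohort` has no rows.")
  if (!all(c("n_fractions", "dose_per_fraction_gy") %in% names(cohort))) {
    stop_invalid("`cohort` needs columns `n_fractions` and `dose_per_fraction_gy`.")
  }
  grid <- alpha_beta_grid(grid)
  m <- vapply(
    grid,
    function(ab) compute_bed(cohort$n_fractions, cohort$dose_per_fraction_gy, ab),
    numeric(nrow(cohort))
  )
  m <- matrix(m, nrow = nrow(cohort), ncol = length(grid))
  colnames(m) <- format(grid, trim = TRUE)
  if ("tumor_id" %in% names(cohort)) rownames(m) <- as.character(cohort$tumor_id)
  m
}
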
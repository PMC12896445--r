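#' Variance inflation factors
#'
#' For each column `j` of a numeric design, regresses that column on all the
#' others by least squares and reports \eqn{\mathrm{VIF}_j = 1/(1 - R_j^2)}.
#' Exact collinearity (auxiliary \eqn{R^2} numerically 1) is reported as
#' `Inf` for the columns involved rather than an error.
#'
#' @param design Data frame or matrix of numeric predictor columns
#'   (at least 2 columns, 3 rows; no constant columns).
#' @return Tibble with `term` and `vif`.
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (!is.numeric(x)) stop_invalid_design("`design` must be numeric.")
  if (nrow(x) < 3) stop_invalid_design("`design` needs at least 3 rows.")
  if (ncol(x) < 2) stop_invalid_design("`design` needs at least 2 columns.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(apply(x, 2, function(col) max(col) == min(col)))) {
    stop_invalid_design("Constant column in `design`.")
  }
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    # collinear designs are legitimate input here (reported as Inf below)
    fit <- suppressWarnings(stats::lsfit(x[, -j, drop = FALSE], x[, j]))
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - ss_res / ss_tot
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = colnames(x), vif = vifs)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the ratio of between-group to
#' within-group mean squares, compared to an F distribution on
#' \eqn{(k - 1, n - k)} degrees of freedom. When every group is the same
#' constant (zero variance everywhere) the statistic is 0 and p = 1.
#'
#' @param data Data frame with a numeric response and a grouping column.
#' @param response,group Unquoted column names.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `n_groups`, `n`.
#' @export
one_way_anova <- function(data, response, group) {
  y <- eval_tidy(enquo(response), data)
  g <- eval_tidy(enquo(group), data)
  if (!is.numeric(y) || any(!is.finite(y))) stop_invalid("`response` must be finite numeric.")
  g <- as.factor(g)
  k <- nlevels(droplevels(g))
  n <- length(y)
  if (k < 2) stop_invalid("Need at least 2 groups.")
  if (n <= k) stop_invalid("Need more observations than groups.")
  grand <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    f <- 0
    p <- 1
  } else if (ss_within == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(
    statistic = f, df_between = df1, df_within = df2,
    p_value = p, n_groups = k, n = n
  )
}
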
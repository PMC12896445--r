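#' Empirical ROC curve of a continuous predictor
#'
#' Builds the empirical receiver operating characteristic curve for a
#' continuous score against a binary outcome, classifying positive when
#' `score >= threshold` (higher score = higher predicted risk). Candidate
#' thresholds are the unique observed scores; the degenerate operating point
#' with sensitivity 0 / specificity 1 (threshold `Inf`) is prepended, and the
#' lowest observed threshold classifies everyone positive (sensitivity 1,
#' specificity 0).
#'
#' @param scores Numeric predictor values (e.g. BED in Gy, PTV in cc, age).
#' @param labels Binary outcome, logical or 0/1; must contain at least one
#'   positive and one negative.
#' @param midpoints If `TRUE`, thresholds are midpoints between adjacent
#'   unique scores instead of the observed scores themselves.
#'
#' @return A tibble of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by decreasing threshold, and
#'   attributes `n_positive`, `n_negative`.
#' @examples
#' empirical_roc(c(5, 7, 7, 9, 11, 13), c(0, 0, 1, 0, 1, 1))
#' @export
empirical_roc <- function(scores, labels, midpoints = FALSE) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop_invalid("`scores` must be finite numeric values.")
  }
  scores <- unname(scores)
  labels <- as_binary_label(labels)
  if (length(scores) != length(labels)) {
    stop_invalid("`scores` and `labels` must have the same length.")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos < 1 || n_neg < 1) {
    stop_degenerate_labels("`labels` must contain both a positive and a negative case.")
  }

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # last index of each block of tied scores -> cumulative TP/FP at that cut
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  thr <- s[last]
  sens <- cumsum(y)[last] / n_pos
  spec <- 1 - cumsum(!y)[last] / n_neg
  if (midpoints && length(thr) > 1) {
    thr <- c(thr[1], (thr[-1] + thr[-length(thr)]) / 2)
  }

  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  structure(curve,
    n_positive = n_pos, n_negative = n_neg,
    class = c("roc_curve", class(curve))
  )
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). For the empirical
#' curve produced by [empirical_roc()] this equals the Mann-Whitney
#' concordance probability: the probability that a randomly chosen positive
#' out-scores a randomly chosen negative, ties counted one-half.
#'
#' @param curve An `roc_curve` from [empirical_roc()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop_invalid("`curve` must be an `roc_curve`.")
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  ord <- order(x, y)
  x <- c(x[ord], 1)
  y <- c(y[ord], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Two-sided p-value for AUC = 0.5
#'
#' Tests the null hypothesis that the predictor carries no information
#' (AUC = 0.5) via the normal approximation to the Mann-Whitney U statistic
#' with the usual tie correction to its null variance. When all scores are
#' tied the statistic sits exactly at its null mean and p = 1.
#'
#' @inheritParams empirical_roc
#' @return Two-sided p-value in (0, 1].
#' @export
auc_pvalue <- function(scores, labels) {
  labels <- as_binary_label(labels)
  if (length(scores) != length(labels)) {
    stop_invalid("`scores` and `labels` must have the same length.")
  }
  n1 <- sum(labels)
  n2 <- sum(!labels)
  if (n1 < 1 || n2 < 1) {
    stop_degenerate_labels("`labels` must contain both a positive and a negative case.")
  }
  n <- n1 + n2
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(scores)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(v)
  min(1, 2 * pnorm(-abs(z)))
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, the vertical distance of an ROC
#' operating point above the chance diagonal.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\]; vectorised.
#' @return J in \[-1, 1\].
#' @examples
#' youden_j(0.750, 0.745)
#' @export
youden_j <- function(sensitivity, specificity) {
  if (!is.numeric(sensitivity) || any(!is.finite(sensitivity)) ||
      any(sensitivity < 0) || any(sensitivity > 1)) {
    stop_invalid("`sensitivity` must lie in [0, 1].")
  }
  if (!is.numeric(specificity) || any(!is.finite(specificity)) ||
      any(specificity < 0) || any(specificity > 1)) {
    stop_invalid("`specificity` must lie in [0, 1].")
  }
  sensitivity + specificity - 1
}

#' Corner-distance optimal ROC operating point
#'
#' Returns the operating point closest (Euclidean distance) to the
#' upper-left corner (sensitivity 1, specificity 1) of ROC space:
#' \eqn{\sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2}}. The two degenerate
#' endpoints (0, 1) and (1, 0) are excluded whenever a non-degenerate point
#' exists. Ties in distance are broken by larger Youden's J, then by the
#' smaller (more dose-conservative) threshold.
#'
#' @param curve An `roc_curve` from [empirical_roc()].
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`, `corner_distance`.
#' @export
corner_optimal <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop_invalid("`curve` must be an `roc_curve`.")
  pts <- tibble::as_tibble(curve)
  degenerate <- (pts$sensitivity == 0 & pts$specificity == 1) |
    (pts$sensitivity == 1 & pts$specificity == 0)
  if (any(!degenerate)) pts <- pts[!degenerate, , drop = FALSE]
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  j <- pts$sensitivity + pts$specificity - 1
  best <- order(d, -j, pts$threshold)[1]
  tibble::tibble(
    threshold = pts$threshold[best],
    sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best],
    youden_j = j[best],
    corner_distance = d[best]
  )
}
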
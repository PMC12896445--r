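#' Plot an ROC curve
#'
#' Step plot of the empirical ROC in (1 - specificity, sensitivity) space
#' with the chance diagonal; the corner-distance optimal operating point is
#' highlighted.
#'
#' @param object An `roc_curve` from [empirical_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[order(1 - df$specificity, df$sensitivity), ]
  opt <- corner_optimal(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(
      data = opt,
      ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity),
      colour = "red", size = 2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Empirical ROC (AUC = %.3f)", roc_auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier cumulative incidence
#'
#' Right-continuous step plot of cumulative incidence (1 - survival), one
#' line per stratum when the curve was estimated with a `by` group.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  grouped <- "group" %in% names(df)
  pad <- function(d) {
    dplyr::bind_rows(
      dplyr::mutate(d[1, ], time = 0, cum_incidence = 0, survival = 1),
      d
    )
  }
  df <- if (grouped) {
    dplyr::bind_rows(lapply(split(df, df$group), pad))
  } else {
    pad(df)
  }
  mapping <- if (grouped) {
    ggplot2::aes(x = .data$time, y = .data$cum_incidence,
                 colour = factor(.data$group))
  } else {
    ggplot2::aes(x = .data$time, y = .data$cum_incidence)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "Days since radiotherapy", y = "Cumulative incidence of PTBE",
      colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an alpha/beta sweep
#'
#' AUC and Youden's J against the alpha/beta ratio, with the
#' highest-J ratio marked.
#'
#' @param object An `ab_sweep` from [sweep_alpha_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ab_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("alpha_beta", "auc", "youden_j")],
    cols = c("auc", "youden_j"), names_to = "metric", values_to = "value"
  )
  best <- select_best_alpha_beta(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha_beta, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = best, linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c(auc = "#1b6ca8", youden_j = "#c0392b"),
      labels = c(auc = "AUC", youden_j = "Youden's J")
    ) +
    ggplot2::labs(
      x = expression(alpha / beta ~ "(Gy)"), y = NULL, colour = NULL,
      title = sprintf("ROC performance across the grid (best = %g Gy)", best)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of Cox hazard ratios
#'
#' @param object A `cox_fit` from [cox_fit()].
#' @param ... Unused.
#' @return A ggplot object with hazard ratios and 95% CIs on a log scale.
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hazard_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci95_low, xmax = .data$ci95_high),
      height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
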
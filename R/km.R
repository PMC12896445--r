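#' Kaplan-Meier estimate of PTBE-free survival and cumulative incidence
#'
#' Product-limit estimator: at each observed time \eqn{t_k} with \eqn{d_k}
#' events among \eqn{n_k} at risk, survival multiplies by
#' \eqn{1 - d_k/n_k}. The curve is right-continuous, starts at
#' \eqn{S(0) = 1}, and steps only at event times; cumulative incidence is
#' \eqn{1 - S(t)}. Subjects censored at a time are still at risk for events
#' at that same time (the usual events-before-censoring convention).
#'
#' @param data Data frame with time and event columns.
#' @param time,event Unquoted column names; default to the cohort schema
#'   columns `time_to_event_days` and `ptbe_event` (1 = PTBE, 0 = censored).
#' @param by Optional unquoted grouping column for stratified curves.
#'
#' @return Tibble of class `km_curve` with one row per distinct observed
#'   time (per stratum): `time`, `n_risk`, `n_event`, `n_censored`,
#'   `survival`, `cum_incidence`, plus the grouping column when `by` is used.
#' @seealso [logrank_test()], [autoplot.km_curve()]
#' @export
km_estimate <- function(data, time = time_to_event_days, event = ptbe_event,
                        by = NULL) {
  time_q <- enquo(time)
  event_q <- enquo(event)
  by_q <- enquo(by)
  t <- eval_tidy(time_q, data)
  e <- eval_tidy(event_q, data)
  if (is.null(t) || length(t) == 0) stop_empty("No observations supplied.")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_invalid("Times must be finite and non-negative.")
  }
  e <- as_binary_label(e, "event")

  one_group <- function(t, e) {
    ut <- sort(unique(t))
    n_event <- vapply(ut, function(u) sum(t == u & e), numeric(1))
    n_cens <- vapply(ut, function(u) sum(t == u & !e), numeric(1))
    n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble::tibble(
      time = ut, n_risk = n_risk, n_event = n_event, n_censored = n_cens,
      survival = surv, cum_incidence = 1 - surv
    )
  }

  if (quo_is_null(by_q)) {
    res <- one_group(t, e)
  } else {
    g <- eval_tidy(by_q, data)
    res <- dplyr::bind_rows(lapply(split(seq_along(t), g), function(idx) {
      out <- one_group(t[idx], e[idx])
      out$group <- g[idx[1]]
      out
    }))
    res <- dplyr::relocate(res, "group")
  }
  structure(res, class = c("km_curve", class(res)))
}

#' Two-group log-rank test
#'
#' Classical observed-minus-expected log-rank statistic over the pooled
#' event times, with hypergeometric variance at each time; the statistic is
#' compared to a chi-square distribution on 1 degree of freedom.
#'
#' @param data Data frame with time, event and group columns.
#' @param group Unquoted column defining exactly two groups.
#' @inheritParams km_estimate
#'
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_events`,
#'   and observed/expected event counts per group.
#' @export
logrank_test <- function(data, group, time = time_to_event_days,
                         event = ptbe_event) {
  t <- eval_tidy(enquo(time), data)
  e <- as_binary_label(eval_tidy(enquo(event), data), "event")
  g <- eval_tidy(enquo(group), data)
  lev <- unique(g)
  if (length(lev) != 2) stop_invalid("`group` must define exactly two groups.")
  if (length(t) == 0) stop_empty("No observations supplied.")
  if (sum(e) == 0) stop_undefined_test("No events in either group; log-rank undefined.")
  in1 <- g == lev[1]

  times <- sort(unique(t[e]))
  o1 <- e1 <- v <- 0
  for (u in times) {
    at_risk <- t >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(t == u & e)
    d1 <- sum(t == u & e & in1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  tibble::tibble(
    statistic = stat, df = 1, p_value = pchisq(stat, 1, lower.tail = FALSE),
    n_events = sum(e),
    observed_1 = o1, expected_1 = e1,
    observed_2 = sum(e) - o1, expected_2 = sum(e) - e1
  )
}
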
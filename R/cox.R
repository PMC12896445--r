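#' Cox proportional hazards regression
#'
#' Fits the semi-parametric proportional-hazards model by Newton-Raphson
#' maximisation of the log partial likelihood, with either the Breslow
#' (default) or Efron correction for tied event times. Standard errors are
#' Wald errors from the inverse observed information at the maximum;
#' hazard ratios and 95% confidence intervals are
#' \eqn{\exp(\hat\beta \pm 1.96\,\mathrm{SE})}.
#'
#' Monotone-likelihood separation (a covariate that perfectly orders the
#' events) does not error: the fit stops with `converged = FALSE` and a
#' diagnostic message, returning the current estimates.
#'
#' @param data Data frame containing the covariates, time and event columns.
#' @param covariates Character vector of covariate names. Character or
#'   factor columns are expanded to treatment-contrast dummies via
#'   `model.matrix()`.
#' @param time,event Column names (strings) for follow-up time and the
#'   event indicator; default to the cohort schema.
#' @param ties Tied-event-time correction, `"breslow"` or `"efron"`.
#' @param max_iter,tol_score,tol_loglik Newton-Raphson controls: iteration
#'   cap and convergence thresholds on the score sup-norm and log-likelihood
#'   change.
#'
#' @return An object of class `cox_fit`: list with a `coefficients` tibble
#'   (`term`, `estimate`, `std_error`, `hazard_ratio`, `ci95_low`,
#'   `ci95_high`, `p_value`), `loglik`, `loglik_null`, `iterations`,
#'   `converged`, `message`, `n`, `n_events`, `ties`. Use [tidy()] /
#'   [glance()] for tabular access.
#' @export
cox_fit <- function(data, covariates, time = "time_to_event_days",
                    event = "ptbe_event", ties = c("breslow", "efron"),
                    max_iter = 30, tol_score = 1e-8, tol_loglik = 1e-10) {
  ties <- match.arg(ties)
  if (!is.data.frame(data) || nrow(data) == 0) stop_empty("`data` has no rows.")
  missing_cols <- setdiff(c(covariates, time, event), names(data))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  t <- data[[time]]
  e <- as_binary_label(data[[event]], event)
  if (sum(e) < 1) stop_invalid("At least one event is required.")
  x <- model.matrix(reformulate(covariates), data = data)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (any(apply(x, 2, function(col) max(col) == min(col)))) {
    stop_invalid_design("Constant covariate column in the design.")
  }
  p <- ncol(x)

  # Log partial likelihood, score and information in one pass. Subjects are
  # processed in decreasing time order so the risk set at each event time is
  # a running cumulative sum.
  eval_pl <- function(beta) {
    eta <- unname(drop(x %*% beta))
    w <- exp(eta)
    ord <- order(t, decreasing = TRUE)
    ll <- 0
    score <- numeric(p)
    info <- matrix(0, p, p)
    s0 <- 0
    s1 <- numeric(p)
    s2 <- matrix(0, p, p)
    i <- 1
    n <- length(t)
    while (i <= n) {
      ti <- t[ord[i]]
      j <- i
      while (j <= n && t[ord[j]] == ti) j <- j + 1
      block <- ord[i:(j - 1)]
      for (k in block) {
        s0 <- s0 + w[k]
        s1 <- s1 + w[k] * x[k, ]
        s2 <- s2 + w[k] * tcrossprod(x[k, ])
      }
      dset <- block[e[block]]
      d <- length(dset)
      if (d > 0) {
        xd <- x[dset, , drop = FALSE]
        ll <- ll + sum(eta[dset])
        if (ties == "breslow" || d == 1) {
          ll <- ll - d * log(s0)
          mu <- s1 / s0
          score <- score + colSums(xd) - d * mu
          info <- info + d * (s2 / s0 - tcrossprod(mu))
        } else {
          wd <- sum(w[dset])
          s1d <- colSums(w[dset] * xd)
          s2d <- matrix(0, p, p)
          for (k in dset) s2d <- s2d + w[k] * tcrossprod(x[k, ])
          score <- score + colSums(xd)
          for (l in 0:(d - 1)) {
            f <- l / d
            s0l <- s0 - f * wd
            s1l <- s1 - f * s1d
            s2l <- s2 - f * s2d
            ll <- ll - log(s0l)
            mu <- s1l / s0l
            score <- score - mu
            info <- info + s2l / s0l - tcrossprod(mu)
          }
        }
      }
      i <- j
    }
    list(loglik = ll, score = score, info = info)
  }

  beta <- numeric(p)
  fit0 <- eval_pl(beta)
  loglik_null <- eval_pl(numeric(p))$loglik
  cur <- fit0
  converged <- FALSE
  msg <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$info, cur$score), error = function(err) NULL)
    if (is.null(step)) {
      msg <- "Singular information matrix; possible separation or collinearity."
      break
    }
    # step halving if the likelihood does not improve
    half <- 0
    repeat {
      beta_new <- beta + step
      new <- eval_pl(beta_new)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      half <- half + 1
      if (half > 20) break
    }
    delta <- new$loglik - cur$loglik
    beta <- beta_new
    cur <- new
    if (any(abs(beta) > 30)) {
      msg <- "Coefficient diverging; monotone likelihood (separation) suspected."
      break
    }
    if (max(abs(cur$score)) < tol_score || abs(delta) < tol_loglik) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.null(msg)) msg <- "Iteration limit reached."

  se <- tryCatch(
    {
      v <- diag(solve(cur$info))
      ifelse(v > 0, sqrt(pmax(v, 0)), NA_real_)
    },
    error = function(err) rep(NA_real_, p)
  )
  coefs <- tibble::tibble(
    term = colnames(x),
    estimate = beta,
    std_error = se,
    hazard_ratio = exp(beta),
    ci95_low = exp(beta - 1.96 * se),
    ci95_high = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(beta / se))
  )
  structure(
    list(
      coefficients = coefs, loglik = cur$loglik, loglik_null = loglik_null,
      iterations = iter, converged = converged, message = msg,
      n = length(t), n_events = sum(e), ties = ties
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox proportional hazards fit (%s ties): n = %d, events = %d\n",
    x$ties, x$n, x$n_events
  ))
  cat(sprintf(
    "log partial likelihood: %.4f (null %.4f), %d iterations, converged: %s\n",
    x$loglik, x$loglik_null, x$iterations, x$converged
  ))
  if (!is.null(x$message)) cat("note:", x$message, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' Broom-style one-row-per-term summary of a [cox_fit()] object.
#'
#' @param x A `cox_fit` object.
#' @param exponentiate If `TRUE`, report hazard ratios (and CI bounds) in
#'   `estimate`; otherwise log-hazard coefficients.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.cox_fit <- function(x, exponentiate = FALSE, ...) {
  co <- x$coefficients
  out <- tibble::tibble(
    term = co$term,
    estimate = if (exponentiate) co$hazard_ratio else co$estimate,
    std.error = co$std_error,
    statistic = co$estimate / co$std_error,
    p.value = co$p_value,
    conf.low = if (exponentiate) co$ci95_low else log(co$ci95_low),
    conf.high = if (exponentiate) co$ci95_high else log(co$ci95_high)
  )
  out
}

#' Glance at a Cox fit
#'
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @return One-row tibble with sample size, event count, log partial
#'   likelihoods, iteration count and convergence flag.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    logLik = x$loglik, logLik_null = x$loglik_null,
    iterations = x$iterations, converged = x$converged
  )
}
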
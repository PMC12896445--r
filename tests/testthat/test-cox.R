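test_that("a covariate with identical event patterns gets beta = 0", {
  d <- tibble::tibble(
    time_to_event_days = rep(c(2, 4, 6, 8), 2),
    ptbe_event = rep(c(1, 0, 1, 1), 2),
    x1 = rep(c(0, 1), each = 4)
  )
  fit <- cox_fit(d, "x1")
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate, 0, tolerance = 1e-10)
  expect_equal(fit$coefficients$hazard_ratio, 1, tolerance = 1e-10)
})

test_that("small no-ties fit matches brute-force likelihood maximisation", {
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- 8
      d <- tibble::tibble(
        time_to_event_days = sample(seq(1, 40), n),
        ptbe_event = c(1, 1, 1, sample(0:1, n - 3, replace = TRUE)),
        x1 = rnorm(n)
      )
      fit <- cox_fit(d, "x1")
      oracle <- stats::optimize(
        function(b) oracle_cox_loglik(b, d$time_to_event_days, d$ptbe_event, d$x1),
        interval = c(-8, 8), maximum = TRUE, tol = 1e-10
      )
      expect_equal(fit$coefficients$estimate, oracle$maximum, tolerance = 1e-5)
      expect_equal(fit$loglik, oracle$objective, tolerance = 1e-8)
    }
  })
})

test_that("coefficients match an established implementation without ties", {
  skip_if_not_installed("survival")
  for (i in 1:50) {
    p <- 1 + (i %% 3)
    d <- rand_surv_data(20 + (i %% 4) * 10, p = p, ties = FALSE, seed = 300 + i)
    if (sum(d$ptbe_event) < 3) next
    fit <- cox_fit(d, paste0("x", seq_len(p)))
    ref <- survival::coxph(
      survival::Surv(time_to_event_days, ptbe_event) ~ .,
      data = d, ties = "breslow",
      control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-12, iter.max = 50)
    )
    expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(
      fit$coefficients$std_error,
      unname(sqrt(diag(stats::vcov(ref)))),
      tolerance = 1e-6
    )
  }
})

test_that("Breslow and Efron tie corrections match the reference", {
  skip_if_not_installed("survival")
  for (i in 1:10) {
    d <- rand_surv_data(40, p = 2, ties = TRUE, seed = 400 + i)
    if (sum(d$ptbe_event) < 5) next
    for (method in c("breslow", "efron")) {
      fit <- cox_fit(d, c("x1", "x2"), ties = method)
      ref <- survival::coxph(
        survival::Surv(time_to_event_days, ptbe_event) ~ x1 + x2,
        data = d, ties = method,
        control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-12, iter.max = 50)
      )
      expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)),
        tolerance = 1e-4
      )
    }
  }
})

test_that("scaling a covariate by c scales beta by 1/c", {
  d <- rand_surv_data(60, p = 1, seed = 32)
  fit1 <- cox_fit(d, "x1")
  d$x1 <- d$x1 * 10
  fit2 <- cox_fit(d, "x1")
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate / 10,
    tolerance = 1e-7
  )
})

test_that("the fit recovers a known per-Gy log-hazard at n = 1000", {
  withr::with_seed(33, {
    n <- 1000
    bed <- runif(n, 20, 120)
    t_ev <- rexp(n, rate = 1e-4 * exp(0.06 * (bed - 70)))
    cens <- runif(n, 100, 2000)
    d <- tibble::tibble(
      time_to_event_days = pmin(t_ev, cens),
      ptbe_event = as.integer(t_ev <= cens),
      bed = bed
    )
    fit <- cox_fit(d, "bed")
    expect_true(fit$converged)
    expect_lt(
      abs(fit$coefficients$estimate - 0.06),
      3 * fit$coefficients$std_error
    )
  })
})

test_that("hazard ratio and CI invariants hold", {
  d <- rand_surv_data(50, p = 2, seed = 34)
  fit <- cox_fit(d, c("x1", "x2"))
  co <- fit$coefficients
  expect_equal(co$hazard_ratio, exp(co$estimate))
  expect_equal(co$ci95_low, exp(co$estimate - 1.96 * co$std_error))
  expect_equal(co$ci95_high, exp(co$estimate + 1.96 * co$std_error))
  expect_true(all(co$ci95_low <= co$hazard_ratio & co$hazard_ratio <= co$ci95_high))
})

test_that("separation yields a diagnostic, not a crash", {
  d <- tibble::tibble(
    time_to_event_days = c(1, 2, 3, 4, 5, 6, 7, 8),
    ptbe_event = c(1, 1, 1, 1, 0, 0, 0, 0),
    x1 = c(5, 4.5, 4, 3.5, 1, 0.8, 0.5, 0.2) # perfectly orders the events
  )
  fit <- cox_fit(d, "x1")
  expect_false(fit$converged)
  expect_match(fit$message, "separation|Singular|Iteration")
})

test_that("invalid Cox designs error and tidy/glance expose the fit", {
  d <- rand_surv_data(30, p = 1, seed = 35)
  d$flat <- 1
  expect_error(cox_fit(d, "flat"), class = "bedsweep_invalid_design")
  d0 <- d
  d0$ptbe_event <- 0L
  expect_error(cox_fit(d0, "x1"), class = "bedsweep_invalid_parameter")

  fit <- cox_fit(d, "x1")
  td <- tidy(fit)
  expect_named(
    td,
    c("term", "estimate", "std.error", "statistic", "p.value", "conf.low", "conf.high")
  )
  expect_equal(tidy(fit, exponentiate = TRUE)$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_true(gl$converged)
})
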
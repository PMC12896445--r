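# Independent oracles used across the suite. All are brute-force or
# first-principles implementations kept deliberately separate from the
# package's code paths.

# AUC as exhaustive pairwise concordance: P(score+ > score-), ties one-half.
oracle_concordance_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Sensitivity/specificity at a threshold by direct confusion-matrix count,
# classifying positive when score >= threshold.
oracle_sens_spec <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  c(
    sensitivity = sum(pred & labels) / sum(labels),
    specificity = sum(!pred & !labels) / sum(!labels)
  )
}

# Exact permutation two-sided p-value for the Mann-Whitney U statistic
# (small n): enumerates every assignment of the positive labels.
oracle_permutation_pvalue <- function(scores, labels) {
  labels <- as.logical(labels)
  n <- length(scores)
  n1 <- sum(labels)
  r <- rank(scores)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(which(labels))
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Explicit Cox log partial likelihood (Breslow form; exact when event times
# are untied), for brute-force maximisation with a single covariate.
oracle_cox_loglik <- function(beta, time, event, x) {
  eta <- x * beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Random survival dataset; untied event times unless ties = TRUE.
rand_surv_data <- function(n, p = 1, ties = FALSE, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("x", seq_len(p))
    beta <- runif(p, -0.8, 0.8)
    t_ev <- rexp(n, rate = 0.1 * exp(drop(x %*% beta)))
    cens <- rexp(n, rate = 0.05)
    time <- pmin(t_ev, cens)
    if (ties) time <- ceiling(time * 2) / 2
    tibble::tibble(
      time_to_event_days = time,
      ptbe_event = as.integer(t_ev <= cens),
      as.data.frame(x)
    )
  })
}

# Fractionation schemes engineered so that BED separates the outcome
# perfectly at alpha/beta = 14 and imperfectly at every other grid ratio:
# near-threshold event/non-event pairs with opposite fractionation flip
# their ordering away from 14.
make_separable_cohort <- function() {
  iso14 <- function(bed, n) isoeffective_dose_per_fraction(bed, n, 14)
  sch <- rbind(
    data.frame(n = c(1, 10, 3, 5), bed14 = c(41.3, 41.6, 48, 55), ev = 1L),
    data.frame(n = c(10, 1, 5, 3), bed14 = c(40.9, 40.6, 35, 30), ev = 0L)
  )
  sch$d <- mapply(iso14, sch$bed14, sch$n)
  sch <- sch[rep(seq_len(nrow(sch)), each = 2), ]
  n <- nrow(sch)
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    tumor_id = sprintf("T%04d", seq_len(n)),
    age_years = seq(45, 69, length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    location = rep(c("convexity", "parasagittal_falcine"), length.out = n),
    gtv_cc = seq(2, 12, length.out = n),
    ptv_cc = seq(2.5, 14, length.out = n),
    bmi = seq(21, 28, length.out = n),
    n_fractions = as.integer(sch$n),
    dose_per_fraction_gy = sch$d,
    ptbe_event = sch$ev,
    time_to_event_days = ifelse(sch$ev == 1, seq(120, 500, length.out = n), 900),
    hypertension = rep(c(0L, 1L), length.out = n),
    diabetes = rep(c(0L, 0L, 1L), length.out = n)
  )
}
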
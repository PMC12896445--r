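test_that("empirical ROC matches brute-force confusion counts", {
  scores <- c(5, 7, 7, 9, 11, 13)
  labels <- c(0, 0, 1, 0, 1, 1)
  curve <- empirical_roc(scores, labels)
  expect_s3_class(curve, "roc_curve")
  expect_equal(attr(curve, "n_positive"), 3)
  expect_equal(attr(curve, "n_negative"), 3)
  # one point per unique score plus the (sens 0, spec 1) endpoint
  expect_equal(nrow(curve), length(unique(scores)) + 1)
  expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$specificity[1], 1)
  for (i in 2:nrow(curve)) {
    oracle <- oracle_sens_spec(scores, labels, curve$threshold[i])
    expect_equal(curve$sensitivity[i], unname(oracle["sensitivity"]))
    expect_equal(curve$specificity[i], unname(oracle["specificity"]))
  }
  # monotone: sens non-decreasing, spec non-increasing as threshold drops
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))
  # both degenerate operating points present
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))
})

test_that("perfect separation and constant scores give the expected curves", {
  curve <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_equal(roc_auc(curve), 1)

  flat <- empirical_roc(rep(2, 5), c(0, 1, 0, 1, 1))
  expect_equal(nrow(flat), 2)
  expect_equal(flat$sensitivity, c(0, 1))
  expect_equal(flat$specificity, c(1, 0))
  expect_equal(roc_auc(flat), 0.5)
  expect_equal(auc_pvalue(rep(2, 5), c(0, 1, 0, 1, 1)), 1)
})

test_that("degenerate labels and malformed input error", {
  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), class = "bedsweep_degenerate_labels")
  expect_error(empirical_roc(1:4, c(0, 0, 0, 0)), class = "bedsweep_degenerate_labels")
  expect_error(empirical_roc(1:4, c(0, 1, 1)), class = "bedsweep_invalid_parameter")
  expect_error(auc_pvalue(1:3, c(1, 1, 1)), class = "bedsweep_degenerate_labels")
})

test_that("trapezoidal AUC equals pairwise concordance with ties half", {
  withr::with_seed(11, {
    for (i in 1:500) {
      n <- sample(4:30, 1)
      scores <- sample(1:10, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      curve <- empirical_roc(scores, labels)
      expect_equal(roc_auc(curve), oracle_concordance_auc(scores, labels),
        tolerance = 1e-12
      )
    }
  })
})

test_that("AUC respects label inversion and monotone score transforms", {
  withr::with_seed(12, {
    scores <- rnorm(40)
    labels <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
    a <- roc_auc(empirical_roc(scores, labels))
    expect_equal(roc_auc(empirical_roc(scores, 1 - labels)), 1 - a, tolerance = 1e-12)
    # strictly increasing transform leaves the ROC geometry unchanged
    a2 <- roc_auc(empirical_roc(exp(scores / 2), labels))
    expect_equal(a2, a, tolerance = 1e-12)
    o1 <- corner_optimal(empirical_roc(scores, labels))
    o2 <- corner_optimal(empirical_roc(exp(scores / 2), labels))
    expect_equal(o2$sensitivity, o1$sensitivity)
    expect_equal(o2$specificity, o1$specificity)
    expect_equal(o2$threshold, exp(o1$threshold / 2), tolerance = 1e-12)
  })
})

test_that("empirical AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (i in 1:10) {
      scores <- rnorm(50)
      labels <- sample(0:1, 50, replace = TRUE, prob = c(0.7, 0.3))
      ours <- roc_auc(empirical_roc(scores, labels))
      ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
        direction = "<", quiet = TRUE
      )))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("AUC p-value is the tie-corrected asymptotic Mann-Whitney test", {
  # exact equivalence with the established asymptotic implementation
  withr::with_seed(15, {
    for (i in 1:25) {
      n <- sample(8:40, 1)
      scores <- sample(1:8, n, replace = TRUE)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      ref <- stats::wilcox.test(
        scores[labels == 1], scores[labels == 0],
        exact = FALSE, correct = FALSE
      )$p.value
      expect_equal(auc_pvalue(scores, labels), ref, tolerance = 1e-12)
    }
  })
  # at tiny n the asymptotic p tracks the exact permutation p only loosely;
  # it remains conservative-side-consistent within the approximation error
  scores <- c(5, 7, 7, 9, 11, 13)
  labels <- c(0, 0, 1, 0, 1, 1)
  p_approx <- auc_pvalue(scores, labels)
  p_exact <- oracle_permutation_pvalue(scores, labels)
  expect_lt(abs(p_approx - p_exact), 0.15)
  # strong separation at 8 vs 8 is decisively non-null
  sep <- c(rnorm(8, 0), rnorm(8, 10))
  expect_lt(auc_pvalue(sep, rep(c(0, 1), each = 8)), 0.01)
})

test_that("corner_optimal picks the closest-to-corner point with tie rules", {
  # a perfect point wins with distance zero
  curve <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  opt <- corner_optimal(curve)
  expect_equal(opt$corner_distance, 0)
  expect_equal(opt$youden_j, 1)
  expect_equal(opt$threshold, 3)

  # symmetric tie: equal distance and J -> smaller threshold wins
  tied <- structure(
    tibble::tibble(
      threshold = c(Inf, 10, 4),
      sensitivity = c(0, 0.6, 0.8),
      specificity = c(1, 0.8, 0.6)
    ),
    n_positive = 5L, n_negative = 5L,
    class = c("roc_curve", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(corner_optimal(tied)$threshold, 4)

  # 200-point curve: exhaustive scan oracle
  withr::with_seed(14, {
    scores <- rnorm(400)
    labels <- sample(0:1, 400, replace = TRUE)
    curve <- empirical_roc(scores, labels)
    opt <- corner_optimal(curve)
    pts <- tibble::as_tibble(curve)
    keep <- !((pts$sensitivity == 0 & pts$specificity == 1) |
      (pts$sensitivity == 1 & pts$specificity == 0))
    pts <- pts[keep, ]
    d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
    j <- pts$sensitivity + pts$specificity - 1
    best <- order(d, -j, pts$threshold)[1]
    expect_equal(opt$threshold, pts$threshold[best])
    expect_equal(opt$corner_distance, min(d))
  })
})

test_that("Youden's J arithmetic and bounds checks", {
  expect_equal(youden_j(0.750, 0.745), 0.495, tolerance = 1e-12)
  expect_equal(youden_j(1, 1), 1)
  expect_equal(youden_j(0.5, 0.5), 0)
  expect_error(youden_j(1.2, 0.5), class = "bedsweep_invalid_parameter")
  expect_error(youden_j(0.5, -0.1), class = "bedsweep_invalid_parameter")
})
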
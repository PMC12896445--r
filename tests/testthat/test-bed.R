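test_that("BED formula matches hand values and LQ monotonicity", {
  # when d equals alpha/beta the BED is exactly twice the physical dose
  expect_equal(compute_bed(1, 10, 10), 20)
  expect_equal(compute_bed(3, 7, 7), 42)
  expect_equal(compute_bed(5, 5, 10), 37.5)
  # BED vanishes with dose
  expect_lt(compute_bed(5, 1e-9, 3), 1e-8)
  # strictly increasing in d and n, strictly decreasing in alpha/beta
  expect_gt(compute_bed(1, 11, 10), compute_bed(1, 10, 10))
  expect_gt(compute_bed(2, 10, 10), compute_bed(1, 10, 10))
  expect_lt(compute_bed(1, 10, 12), compute_bed(1, 10, 10))
})

test_that("invalid LQ parameters are rejected", {
  expect_error(compute_bed(1, -1, 10), class = "bedsweep_invalid_parameter")
  expect_error(compute_bed(0, 1, 10), class = "bedsweep_invalid_parameter")
  expect_error(compute_bed(1, 1, 0), class = "bedsweep_invalid_parameter")
  expect_error(compute_bed(1.5, 1, 10), class = "bedsweep_invalid_parameter")
  expect_error(
    isoeffective_dose_per_fraction(-5, 1, 10),
    class = "bedsweep_invalid_parameter"
  )
  expect_error(
    isoeffective_dose_per_fraction(40, 1, -2),
    class = "bedsweep_invalid_parameter"
  )
  expect_error(alpha_beta_grid(c(3, 3)), class = "bedsweep_invalid_parameter")
  expect_error(alpha_beta_grid(c(-1, 2)), class = "bedsweep_invalid_parameter")
})

test_that("isoeffective inversion agrees with the quadratic-root oracle", {
  # positive root of d^2 + ab*d - ab*BED/n = 0 via polyroot, frozen cases
  cases <- list(
    c(bed = 40.595, n = 1, ab = 14),
    c(bed = 40.595, n = 5, ab = 14),
    c(bed = 119.840, n = 1, ab = 2),
    c(bed = 55, n = 8, ab = 7.3)
  )
  for (cs in cases) {
    roots <- polyroot(c(-cs["ab"] * cs["bed"] / cs["n"], cs["ab"], 1))
    d_oracle <- Re(roots[abs(Im(roots)) < 1e-8 & Re(roots) > 0])
    expect_equal(
      isoeffective_dose_per_fraction(cs["bed"], cs["n"], cs["ab"]),
      d_oracle,
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
  # trivial inverse of the doubling case
  expect_equal(isoeffective_dose_per_fraction(20, 1, 10), 10)
  # the single-fraction cutoff quoted to 3 decimals round-trips to its BED
  expect_equal(compute_bed(1, 17.846, 14), 40.595, tolerance = 0.005)
})

test_that("BED and its inversion round-trip below 1e-9 Gy", {
  withr::with_seed(41, {
    bed <- runif(1000, 1, 200)
    n <- sample(1:20, 1000, replace = TRUE)
    ab <- runif(1000, 1, 30)
    d <- isoeffective_dose_per_fraction(bed, n, ab)
    expect_lt(max(abs(compute_bed(n, d, ab) - bed)), 1e-9)
  })
})

test_that("large alpha/beta limit recovers physical dose", {
  expect_equal(compute_bed(5, 6, 1e9), 30, tolerance = 1e-6)
  expect_equal(isoeffective_dose_per_fraction(45, 5, 1e9), 9, tolerance = 1e-6)
})

test_that("dose per fraction decreases with fraction number at fixed BED", {
  d <- isoeffective_dose_per_fraction(60, 1:15, 10)
  expect_true(all(diff(d) < 0))
})

test_that("bed_matrix tabulates the scalar formula over cohort x grid", {
  cohort <- tibble::tibble(
    n_fractions = c(1L, 5L, 10L),
    dose_per_fraction_gy = c(18, 5.8, 3)
  )
  grid <- c(3, 10, 14)
  m <- bed_matrix(cohort, grid = grid)
  expect_equal(dim(m), c(3, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(
        unname(m[i, j]),
        compute_bed(cohort$n_fractions[i], cohort$dose_per_fraction_gy[i], grid[j])
      )
    }
  }
  one <- bed_matrix(
    tibble::tibble(n_fractions = 1L, dose_per_fraction_gy = 10),
    grid = 10
  )
  expect_equal(unname(one[1, 1]), 20)
})

test_that("bed_matrix rows strictly decrease in alpha/beta; bad input errors", {
  cohort <- tibble::tibble(n_fractions = c(1L, 4L), dose_per_fraction_gy = c(16, 6))
  m <- bed_matrix(cohort, 2:20)
  expect_equal(dim(m), c(2, 19))
  expect_true(all(apply(m, 1, function(r) all(diff(r) < 0))))
  expect_true(all(m > 0))
  expect_error(bed_matrix(cohort[0, ], 2:20), class = "bedsweep_empty_input")
  expect_error(bed_matrix(data.frame(x = 1), 2:20), class = "bedsweep_invalid_parameter")
})
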
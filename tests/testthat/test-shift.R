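test_that("profile normalization produces shares and rejects empty profiles", {
  expect_equal(normalize_profile(c(2, 6, 2, 0, 0, 0, 0, 0, 0)),
               c(0.2, 0.6, 0.2, 0, 0, 0, 0, 0, 0))
  expect_equal(normalize_profile(c(5, NA, 5, 0, 0)),
               c(0.5, 0, 0.5, 0, 0))
  expect_error(normalize_profile(rep(NA_real_, 9)),
               class = "diffpop_unscorable")
  expect_error(normalize_profile(rep(0, 9)), class = "diffpop_unscorable")
  expect_error(normalize_profile(c(1, NA, 1), missing_policy = "error"),
               class = "diffpop_unscorable")
  expect_error(normalize_profile(c(1, -1, 2)),
               class = "diffpop_validation_error")
})

test_that("KS shift statistic matches hand-derived values and is symmetric", {
  a <- c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0)
  b <- c(0, 0.5, 0.5, 0, 0, 0, 0, 0, 0)
  expect_equal(ks_shift_statistic(a, a), 0)
  expect_equal(ks_shift_statistic(a, b), 0.5)
  expect_equal(ks_shift_statistic(b, a), 0.5)

  all2 <- c(0, 1, rep(0, 7))
  all3 <- c(0, 0, 1, rep(0, 6))
  expect_equal(ks_shift_statistic(all2, all3), 1)

  expect_error(ks_shift_statistic(a, b[1:5]),
               class = "diffpop_validation_error")
  expect_error(ks_shift_statistic(a, a * 2),
               class = "diffpop_validation_error")
})

test_that("KS statistic agrees with the brute-force prefix-sum oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      a <- random_profile()
      b <- random_profile()
      expect_equal(ks_shift_statistic(a, b), brute_force_ks(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("D, centroid and peak are invariant to raw-profile scaling", {
  withr::with_seed(7, {
    raw_a <- stats::rexp(9)
    raw_b <- stats::rexp(9)
    for (const in c(0.01, 3, 1e6)) {
      na1 <- normalize_profile(raw_a)
      na2 <- normalize_profile(raw_a * const)
      expect_equal(na1, na2, tolerance = 1e-12)
      d1 <- ks_shift_statistic(na1, normalize_profile(raw_b))
      d2 <- ks_shift_statistic(na2, normalize_profile(raw_b * const))
      expect_equal(d1, d2, tolerance = 1e-12)
      expect_equal(shift_direction(na1, normalize_profile(raw_b)),
                   shift_direction(na2, normalize_profile(raw_b * const)))
    }
  })
})

test_that("shift direction reports centroids on the solvent scale and 1-based peaks", {
  design <- fractionation_design()
  veh <- c(0, 1, rep(0, 7))   # all mass in fraction 2
  cmp <- c(0, 0, 1, rep(0, 6)) # all mass in fraction 3
  dir <- shift_direction(veh, cmp, design)
  expect_equal(dir$centroid_shift, 11.98 - 6.45)
  expect_equal(dir$peak_vehicle, 2)
  expect_equal(dir$peak_compound, 3)
  expect_true(dir$stabilized)

  same <- shift_direction(veh, veh, design)
  expect_equal(same$centroid_shift, 0)
  expect_false(same$stabilized)

  rev <- shift_direction(cmp, veh, design)
  expect_equal(rev$centroid_shift, -(11.98 - 6.45))
  expect_false(rev$stabilized)

  # argmax ties break to the lowest fraction
  tied <- rep(1 / 9, 9)
  expect_equal(shift_direction(tied, tied, design)$peak_vehicle, 1)
})

test_that("replicate reproducibility is the minimum pairwise Spearman rho", {
  x <- c(1, 5, 2, 8, 3, 9, 4, 7, 6)
  expect_equal(replicate_reproducibility(cbind(x, x)), 1)
  # a rank-reversed replicate is perfectly anticorrelated
  expect_equal(replicate_reproducibility(cbind(1:9, 9:1)), -1)
  # rank-identical sequences correlate perfectly
  expect_equal(replicate_reproducibility(cbind(1:9, 2 * (1:9))), 1)
  # the minimum over pairs governs
  m <- cbind(1:9, 1:9, 9:1)
  expect_equal(replicate_reproducibility(m), -1)
  # zero-variance replicate -> undefined, fails any gate
  expect_true(is.na(replicate_reproducibility(cbind(x, rep(2, 9)))))
  expect_error(replicate_reproducibility(matrix(1:9, ncol = 1)),
               class = "diffpop_validation_error")
})

test_that("permutation p-value separates real shifts from exchangeable noise", {
  strong_veh <- cbind(c(8, 2, 0, 0), c(9, 1, 0, 0), c(7, 3, 0, 0))
  strong_cmp <- cbind(c(0, 0, 2, 8), c(0, 0, 1, 9), c(0, 0, 3, 7))
  res <- ks_permutation_pvalue(cbind(strong_veh, strong_cmp),
                               rep(c("vehicle", "compound"), each = 3))
  expect_lte(res$p_value, 2 / 20 + 1e-12)  # only the labeling and its mirror
  expect_gt(res$d_observed, 0.9)

  withr::with_seed(1, {
    null_mat <- matrix(stats::rexp(4 * 6), nrow = 4)
  })
  res0 <- ks_permutation_pvalue(null_mat,
                                rep(c("vehicle", "compound"), each = 3))
  expect_gte(res0$p_value, 1 / 20)
})
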
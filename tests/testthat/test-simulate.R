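test_that("precipitation profile distributes mass along the ladder", {
  design <- fractionation_design()

  # saturated curve: midpoint far below the first step, very steep
  p <- precipitation_profile(midpoint = 1, steepness = 50, abundance = 10,
                             design = design)
  expect_equal(p$intensity[1], 10, tolerance = 1e-9)
  expect_true(all(p$intensity[-1] < 1e-9))

  # shifted = TRUE with zero delta is the identity
  a <- precipitation_profile(25, 0.3, 5, design, shift_delta = 0,
                             shifted = FALSE)
  b <- precipitation_profile(25, 0.3, 5, design, shift_delta = 0,
                             shifted = TRUE)
  expect_identical(a, b)

  # the fraction covering (19.80, 30.53] captures exactly half the mass
  # when the logistic is centred on that interval with F spanning
  # 0.25 -> 0.75 across it (hand-derived from the logistic quartiles)
  midpoint <- (19.80 + 30.53) / 2
  steepness <- 2 * log(3) / (30.53 - 19.80)
  p <- precipitation_profile(midpoint, steepness, abundance = 1, design)
  expect_equal(p$intensity[5], 0.5, tolerance = 1e-12)

  expect_error(precipitation_profile(25, 0.3, 1, c(10, 5, 20)),
               class = "diffpop_validation_error")
  expect_error(precipitation_profile(25, -1, 1, design),
               class = "diffpop_validation_error")
})

test_that("summed fraction mass conserves abundance when the ladder covers the curve", {
  design <- fractionation_design()
  for (mid in c(25, 35, 50)) {
    p <- precipitation_profile(mid, steepness = 1, abundance = 7.5,
                               design = design)
    expect_equal(sum(p$intensity), 7.5, tolerance = 1e-9)
  }
})

test_that("diffpop simulator is deterministic and honest about its truth table", {
  s1 <- simulate_diffpop(n_proteins = 40, n_targets = 3, noise_cv = 0.2,
                         seed = 11)
  s2 <- simulate_diffpop(n_proteins = 40, n_targets = 3, noise_cv = 0.2,
                         seed = 11)
  expect_identical(s1, s2)
  expect_equal(sum(s1$truth$is_target), 3)
  expect_true(all(s1$truth$shift_delta[s1$truth$is_target] > 0))
  expect_equal(nrow(s1$data), 40 * 2 * 3 * 9)

  s3 <- simulate_diffpop(n_proteins = 40, n_targets = 3, noise_cv = 0.2,
                         seed = 12)
  expect_false(identical(s1$data$intensity, s3$data$intensity))
})

test_that("without noise or targets the two conditions are identical", {
  sim <- simulate_diffpop(n_proteins = 25, n_targets = 0, noise_cv = 0,
                          seed = 5)
  wide <- tidyr::pivot_wider(sim$data,
                             id_cols = c("protein_id", "replicate",
                                         "fraction_index"),
                             names_from = "condition",
                             values_from = "intensity")
  expect_equal(wide$vehicle, wide$compound)
})

test_that("dropout records sub-threshold values as missing", {
  sim <- simulate_diffpop(n_proteins = 30, n_targets = 0, noise_cv = 0,
                          dropout_threshold = 1e4, seed = 2)
  expect_true(any(sim$data$is_missing))
  expect_true(all(is.na(sim$data$intensity[sim$data$is_missing])))
  expect_true(all(sim$data$intensity[!sim$data$is_missing] >= 1e4))
  expect_error(simulate_diffpop(n_proteins = 5, n_targets = 9, seed = 1),
               class = "diffpop_validation_error")
})

test_that("TMT simulator plants exact effects and calibrated missingness", {
  sim <- simulate_tmt(n_proteins = 60, n_regulated = 6,
                      log2fc_planted = 0.5, sigma = 0, missing_rate = 0,
                      seed = 3)
  m <- as.matrix(sim$matrix[, tmt_channel_map()$channel])
  l2 <- log2(m)
  fc <- rowMeans(l2[, c(2, 4, 6)]) - rowMeans(l2[, c(1, 3, 5)])
  expect_equal(fc[sim$truth$is_regulated], rep(0.5, 6),
               ignore_attr = TRUE)
  expect_equal(fc[!sim$truth$is_regulated],
               rep(0, sum(!sim$truth$is_regulated)), ignore_attr = TRUE)

  # observed missingness within 3 binomial SEs of the nominal rate
  rate <- 0.1
  sim2 <- simulate_tmt(n_proteins = 2000, n_regulated = 0, sigma = 0.2,
                       missing_rate = rate, seed = 4)
  m2 <- as.matrix(sim2$matrix[, tmt_channel_map()$channel])
  n <- length(m2)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(is.na(m2)) - rate), 3 * se)

  expect_error(simulate_tmt(missing_rate = 1), class = "diffpop_validation_error")
  expect_error(simulate_tmt(missing_rate = -0.1),
               class = "diffpop_validation_error")
})

test_that("DIA panel enforces the shared-core contract", {
  expect_error(
    simulate_dia_panel(n_proteins = 20,
                       shared_core_ids = c("P0001", "P0002"),
                       per_line_regulated = list(OVCAR3 = "P0001",
                                                 OV231 = c("P0001", "P0002"),
                                                 PEO1 = c("P0001", "P0002"),
                                                 `OV81.2` = c("P0001", "P0002")),
                       seed = 1),
    class = "diffpop_validation_error"
  )
  sim <- simulate_dia_panel(n_proteins = 40, seed = 2)
  expect_named(sim$matrices, c("OVCAR3", "OV231", "PEO1", "OV81.2"))
  expect_equal(nrow(sim$condition_map), 12)
  expect_equal(sum(sim$condition_map$condition == "vehicle"), 6)
  core <- unique(sim$truth$protein_id[sim$truth$in_shared_core])
  expect_length(core, 14)
  reg_all <- table(sim$truth$protein_id[sim$truth$is_regulated])
  expect_true(all(reg_all[core] == 4))
})

test_that("PK simulator reproduces the one-compartment closed forms", {
  prof <- simulate_pk_profile(dose = 1, volume = 0.1,
                              elimination_rate = log(2),
                              times = c(1, 2, 4))
  expect_equal(prof$conc, c(5, 2.5, 0.625))

  expect_error(
    simulate_pk_profile(dose = 1, volume = 0.1, elimination_rate = 0.5,
                        absorption_rate = 0.5),
    class = "diffpop_validation_error"
  )

  # LLOQ above everything flags every point
  prof2 <- simulate_pk_profile(dose = 1, volume = 1, elimination_rate = 1,
                               lloq = 100)
  expect_true(all(prof2$below_lloq))
  expect_error(nca(prof2, dose = 1, route = "iv"),
               class = "diffpop_validation_error")
})
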
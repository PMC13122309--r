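test_that("trapezoidal AUC matches hand geometry and is additive", {
  expect_equal(auc_trapezoid(c(0, 1), c(1, 1)), 1)
  expect_equal(auc_trapezoid(c(0, 2), c(0, 2)), 2)

  withr::with_seed(5, {
    t <- sort(runif(12, 0, 24))
    c_ <- rexp(12)
  })
  whole <- auc_trapezoid(t, c_)
  expect_equal(auc_trapezoid(t[1:6], c_[1:6]) +
                 auc_trapezoid(t[6:12], c_[6:12]), whole)

  # inserting a collinear interior point changes nothing
  tm <- (t[3] + t[4]) / 2
  cm <- c_[3] + (c_[4] - c_[3]) * (tm - t[3]) / (t[4] - t[3])
  t2 <- append(t, tm, after = 3)
  c2 <- append(c_, cm, after = 3)
  expect_equal(auc_trapezoid(t2, c2), whole)

  expect_error(auc_trapezoid(1, 1), class = "diffpop_validation_error")
  expect_error(auc_trapezoid(c(0, 0), c(1, 1)),
               class = "diffpop_validation_error")
})

test_that("terminal slope regression recovers exact exponentials", {
  t <- c(0, 0.5, 1, 2, 4, 8)
  conc <- 10 * exp(-0.6931 * t)
  fit <- fit_lambda_z(t, conc)
  expect_equal(fit$lambda_z, 0.6931, tolerance = 1e-12)
  expect_equal(fit$t_half, log(2) / 0.6931, tolerance = 1e-12)

  # a 3-point terminal window of a mono-exponential gives the same slope
  fit3 <- fit_lambda_z(t[1:4], conc[1:4])
  expect_equal(fit3$lambda_z, fit$lambda_z, tolerance = 1e-12)

  expect_error(fit_lambda_z(t, rep(5, 6)),
               class = "diffpop_no_elimination")
  # a rising profile has its maximum at the end: no terminal phase exists
  expect_error(fit_lambda_z(t, 10 * exp(0.2 * t)),
               class = "diffpop_error")
  expect_error(fit_lambda_z(c(0, 1, 2), c(3, 2, 1)),
               class = "diffpop_validation_error")
})

test_that("IV NCA recovers clearance and volume from dense exact sampling", {
  v <- 0.1   # L/kg scale
  k <- 0.6931
  times <- c(0, exp(seq(log(0.01), log(30), length.out = 500)))
  prof <- simulate_pk_profile(dose = 1, volume = v, elimination_rate = k,
                              times = times)
  res <- nca(prof, dose = 1, route = "iv")
  expect_equal(res$t_half, log(2) / res$lambda_z)  # identity, exact
  expect_equal(res$lambda_z, k, tolerance = 1e-9)
  expect_lt(abs(res$cl - v * k) / (v * k), 0.01)
  expect_lt(abs(res$vd_ss - v) / v, 0.01)
  expect_equal(res$c0, 10, tolerance = 1e-6)
  expect_gte(res$auc_inf, res$auc_last)
})

test_that("IV back-extrapolation supplies C0 when sampling starts late", {
  k <- 0.5
  prof <- simulate_pk_profile(dose = 2, volume = 0.2,
                              elimination_rate = k,
                              times = c(0.083, 0.25, 0.5, 1, 2, 4, 8, 24))
  res <- nca(prof, dose = 2, route = "iv")
  expect_equal(res$c0, 10, tolerance = 1e-9)
})

test_that("IP NCA reports the observed maximum and skips clearance", {
  prof <- simulate_pk_profile(dose = 10, volume = 0.1,
                              elimination_rate = 0.8,
                              absorption_rate = 3,
                              times = c(0.25, 0.5, 1, 2, 4, 8, 24))
  res <- nca(prof, dose = 10, route = "ip")
  expect_equal(res$tmax, prof$time_h[which.max(prof$conc)])
  expect_equal(res$cmax, max(prof$conc))
  expect_true(is.na(res$cl))
  expect_true(is.na(res$vd_ss))
})

test_that("LLOQ-flagged points are excluded from every computation", {
  times <- c(0.083, 0.25, 0.5, 1, 2, 4, 8, 24)
  prof <- simulate_pk_profile(dose = 1, volume = 0.1,
                              elimination_rate = 0.4, times = times,
                              lloq = 0.1)
  expect_true(any(prof$below_lloq))
  res <- nca(prof, dose = 1, route = "iv")
  expect_equal(nrow(res$data), sum(!prof$below_lloq))
  expect_true(all(res$data$conc >= 0.1))
})

test_that("bioavailability identities hold", {
  iv <- simulate_pk_profile(dose = 1, volume = 0.1,
                            elimination_rate = 0.5)
  auc_iv <- auc_trapezoid(iv$time_h, iv$conc)
  # a profile scaled by the dose ratio is 100% bioavailable by construction
  expect_equal(
    bioavailability(list(auc = auc_iv, dose = 1),
                    list(auc = 10 * auc_iv, dose = 10)),
    100
  )
  expect_equal(
    bioavailability(list(auc = auc_iv, dose = 1),
                    list(auc = 5 * auc_iv, dose = 10)),
    50
  )
  # invariant to rescaling both profiles' concentration units
  expect_equal(
    bioavailability(list(auc = auc_iv * 1e3, dose = 1),
                    list(auc = 10 * auc_iv * 1e3, dose = 10)),
    100
  )
  expect_error(bioavailability(list(auc = 0, dose = 1),
                               list(auc = 1, dose = 1)),
               class = "diffpop_validation_error")

  # complete first-order absorption: dose-normalized Bateman AUC matches IV
  k <- 0.8
  times <- c(0, exp(seq(log(0.005), log(60), length.out = 800)))
  ivp <- simulate_pk_profile(dose = 1, volume = 0.1, elimination_rate = k,
                             times = times)
  ipp <- simulate_pk_profile(dose = 10, volume = 0.1,
                             elimination_rate = k, absorption_rate = 4,
                             times = times)
  res_iv <- nca(ivp, dose = 1, route = "iv")
  res_ip <- nca(ipp, dose = 10, route = "ip")
  f <- bioavailability(res_iv, res_ip, which_auc = "auc_inf")
  expect_lt(abs(f - 100), 1)
})

test_that("time above a threshold uses log-linear crossings", {
  expect_equal(time_above_threshold(c(0, 4), c(2, 0.5), 1), 2)
  expect_equal(time_above_threshold(c(0, 2, 5), c(0.2, 0.5, 0.1), 1), 0)
  expect_equal(time_above_threshold(c(0, 3, 7), c(5, 4, 2), 1), 7)
  expect_error(time_above_threshold(c(0, 1), c(1, 2), 0),
               class = "diffpop_validation_error")
})

test_that("NCA summaries tidy into tables", {
  prof <- simulate_pk_profile(dose = 1, volume = 0.1,
                              elimination_rate = 0.5)
  res <- nca(prof, dose = 1, route = "iv", threshold = 1)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$cl, res$cl)
  td <- tidy(res)
  expect_true(all(c("auc_last", "t_half", "cl") %in% td$parameter))
  expect_gt(res$time_above_threshold, 0)
})
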
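#' Linear trapezoidal area under a concentration-time curve
#'
#' @param times Strictly increasing times (h), >= 2 usable points.
#' @param conc Concentrations at `times` (no missing values).
#'
#' @return AUC from the first to the last point (conc x h).
#' @examples
#' auc_trapezoid(c(0, 1), c(1, 1))
#' @export
auc_trapezoid <- function(times, conc) {
  check_profile_vectors(times, conc)
  sum(diff(times) * (head(conc, -1) + tail(conc, -1)) / 2)
}

# First-moment curve (t * C) by the same rule; used for MRT / VDss.
aumc_trapezoid <- function(times, conc) {
  auc_trapezoid(times, times * conc)
}

#' Terminal elimination slope by best-adjusted-R2 log-linear regression
#'
#' Fits `log(conc) ~ time` on candidate terminal windows -- every suffix
#' of at least `min_points` observations strictly after the concentration
#' maximum -- and keeps the window with the best adjusted R2 among those
#' with a negative slope (ties go to the longer window). `lambda_z` is the
#' negated slope.
#'
#' @param times Strictly increasing times (h).
#' @param conc Positive concentrations (points in any candidate window
#'   must be positive for the log fit).
#' @param min_points Minimum window size (>= 3).
#'
#' @return List with `lambda_z` (1/h), `t_half` (h), `intercept` (log
#'   scale), `n_points`, `adj_r2`, and `window` (time range used).
#' @examples
#' t <- c(0, 0.5, 1, 2, 4, 8)
#' fit_lambda_z(t, 10 * exp(-0.6931 * t))
#' @export
fit_lambda_z <- function(times, conc, min_points = 3) {
  check_profile_vectors(times, conc)
  min_points <- check_count(min_points, "min_points", min = 3L)
  n <- length(times)
  imax <- which.max(conc)
  if (imax + 1L > n - min_points + 1L) {
    stop_diffpop("too few terminal points after Cmax for a slope fit",
                 class = "diffpop_validation_error")
  }
  starts <- seq(imax + 1L, n - min_points + 1L)
  best <- NULL
  for (s in starts) {
    idx <- s:n
    cw <- conc[idx]
    if (any(cw <= 0)) {
      stop_diffpop("non-positive concentration in a terminal window",
                   class = "diffpop_validation_error")
    }
    y <- log(cw)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) next  # flat window: no decline to fit
    fit <- lm(y ~ times[idx])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    r2 <- 1 - sum(resid(fit)^2) / sst
    k <- length(idx)
    adj_r2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj_r2 > best$adj_r2 + 1e-10 ||
        (abs(adj_r2 - best$adj_r2) <= 1e-10 && k > best$n_points)) {
      best <- list(
        lambda_z = -slope,
        t_half = log(2) / -slope,
        intercept = unname(coef(fit)[1]),
        n_points = k,
        adj_r2 = adj_r2,
        window = range(times[idx])
      )
    }
  }
  if (is.null(best)) {
    stop_diffpop("no declining terminal phase found (slope >= 0)",
                 class = "diffpop_no_elimination")
  }
  best
}

#' Noncompartmental analysis of a plasma concentration-time profile
#'
#' Points flagged below the limit of quantification (or below `lloq`) are
#' excluded from every computation. For an IV bolus, the concentration at
#' time zero is back-extrapolated log-linearly from the first two usable
#' points and prepended for integration; `AUC_inf = AUC_last +
#' C_last / lambda_z`, clearance is `dose / AUC_inf`, and the steady-state
#' volume is `CL * MRT` with `MRT = AUMC_inf / AUC_inf`. For an
#' extravascular (e.g. IP) profile, `Cmax`/`Tmax` come from the observed
#' maximum (ties to the earliest time) and clearance/volume are not
#' reported.
#'
#' Units follow the inputs: with dose in amount/kg and concentration in
#' amount/volume, clearance comes out in volume/h/kg and the steady-state
#' volume in volume/kg.
#'
#' @param data Tibble with `time_h`, `conc`, and optionally `below_lloq`.
#' @param dose Administered dose per kg.
#' @param route `"iv"` (bolus) or `"ip"` (extravascular).
#' @param lloq Lower limit of quantification; `NULL` relies on the
#'   `below_lloq` column alone.
#' @param threshold Optional therapeutic concentration; when given, the
#'   time spent above it is reported (see [time_above_threshold()]).
#'
#' @return An object of class `nca_result`; see [glance.nca_result()] for
#'   the one-row summary.
#' @examples
#' prof <- simulate_pk_profile(dose = 1, volume = 0.1,
#'                             elimination_rate = log(2))
#' nca(prof, dose = 1, route = "iv")
#' @export
nca <- function(data, dose, route = c("iv", "ip"), lloq = NULL,
                threshold = NULL) {
  route <- match.arg(route)
  check_number(dose, "dose", min = 0, allow_min = FALSE)
  if (!is.data.frame(data) || !all(c("time_h", "conc") %in% names(data))) {
    stop_diffpop("`data` needs columns `time_h` and `conc`",
                 class = "diffpop_schema_error")
  }
  usable <- !is.na(data$conc)
  if ("below_lloq" %in% names(data)) {
    usable <- usable & !data$below_lloq
  }
  if (!is.null(lloq)) {
    check_number(lloq, "lloq", min = 0)
    usable <- usable & data$conc >= lloq
  }
  times <- data$time_h[usable]
  conc <- data$conc[usable]
  if (length(times) < 2L) {
    stop_diffpop("fewer than 2 quantifiable points; cannot run NCA",
                 class = "diffpop_validation_error")
  }
  check_profile_vectors(times, conc)

  lam <- fit_lambda_z(times, conc)
  lambda_z <- lam$lambda_z

  c0 <- NA_real_
  cmax <- NA_real_
  tmax <- NA_real_
  int_times <- times
  int_conc <- conc
  if (route == "iv") {
    # log-linear back-extrapolation through the first two points
    b <- (log(conc[2]) - log(conc[1])) / (times[2] - times[1])
    c0 <- exp(log(conc[1]) - b * times[1])
    if (times[1] > 0) {
      int_times <- c(0, times)
      int_conc <- c(c0, conc)
    }
  } else {
    cmax <- max(conc)
    tmax <- times[which.max(conc)]
  }

  auc_last <- auc_trapezoid(int_times, int_conc)
  aumc_last <- aumc_trapezoid(int_times, int_conc)
  c_last <- conc[length(conc)]
  t_last <- times[length(times)]
  auc_inf <- auc_last + c_last / lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lambda_z +
    c_last / lambda_z^2
  mrt <- aumc_inf / auc_inf
  cl <- if (route == "iv") dose / auc_inf else NA_real_
  vd_ss <- if (route == "iv") cl * mrt else NA_real_
  t_above <- if (!is.null(threshold)) {
    time_above_threshold(int_times, int_conc, threshold)
  } else {
    NA_real_
  }

  structure(
    list(
      route = route, dose = dose,
      c0 = c0, cmax = cmax, tmax = tmax,
      auc_last = auc_last, auc_inf = auc_inf,
      aumc_last = aumc_last, aumc_inf = aumc_inf,
      lambda_z = lambda_z, t_half = log(2) / lambda_z,
      mrt = mrt, cl = cl, vd_ss = vd_ss,
      time_above_threshold = t_above, threshold = threshold,
      lambda_fit = lam, n_points = length(times),
      data = tibble(time_h = times, conc = conc)
    ),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("Noncompartmental PK summary (%s, dose %.4g/kg)\n",
              toupper(x$route), x$dose))
  if (x$route == "iv") {
    cat(sprintf("  C0 %.4g   CL %.4g /h/kg   VDss %.4g /kg\n",
                x$c0, x$cl, x$vd_ss))
  } else {
    cat(sprintf("  Cmax %.4g at Tmax %.4g h\n", x$cmax, x$tmax))
  }
  cat(sprintf("  AUC_last %.4g   AUC_inf %.4g   lambda_z %.4g /h   T1/2 %.4g h\n",
              x$auc_last, x$auc_inf, x$lambda_z, x$t_half))
  if (!is.na(x$time_above_threshold)) {
    cat(sprintf("  time above %.4g: %.4g h\n", x$threshold,
                x$time_above_threshold))
  }
  invisible(x)
}

#' One-row summary of an NCA result
#'
#' @param x An `nca_result` object.
#' @param ... Unused.
#' @return A one-row tibble with the NCA quantities.
#' @method glance nca_result
#' @export
glance.nca_result <- function(x, ...) {
  tibble(
    route = x$route, dose = x$dose, c0 = x$c0, cmax = x$cmax,
    tmax = x$tmax, auc_last = x$auc_last, auc_inf = x$auc_inf,
    lambda_z = x$lambda_z, t_half = x$t_half, mrt = x$mrt, cl = x$cl,
    vd_ss = x$vd_ss, time_above_threshold = x$time_above_threshold,
    n_points = x$n_points
  )
}

#' @rdname glance.nca_result
#' @method tidy nca_result
#' @export
tidy.nca_result <- function(x, ...) {
  g <- glance(x)
  num <- g[, !vapply(g, is.character, logical(1))]
  tibble(parameter = names(num), value = as.numeric(num[1, ]))
}

#' Absolute bioavailability from dose-normalized AUCs
#'
#' `F(%) = 100 * (AUC_ev / dose_ev) / (AUC_iv / dose_iv)`, comparing an
#' extravascular (e.g. IP) profile against the IV reference.
#'
#' @param iv,ev Either `nca_result` objects or lists with elements `auc`
#'   and `dose`.
#' @param which_auc `"auc_last"` (default) or `"auc_inf"` when
#'   `nca_result` objects are supplied.
#'
#' @return Bioavailability in percent.
#' @examples
#' bioavailability(list(auc = 10, dose = 1), list(auc = 100, dose = 10))
#' @export
bioavailability <- function(iv, ev, which_auc = c("auc_last", "auc_inf")) {
  which_auc <- match.arg(which_auc)
  get <- function(x) {
    if (inherits(x, "nca_result")) {
      list(auc = x[[which_auc]], dose = x$dose)
    } else if (is.list(x) && all(c("auc", "dose") %in% names(x))) {
      x
    } else {
      stop_diffpop(
        "arguments must be nca_result objects or lists with auc and dose",
        class = "diffpop_validation_error"
      )
    }
  }
  a <- get(iv)
  b <- get(ev)
  if (a$auc <= 0 || b$auc <= 0) {
    stop_diffpop("AUCs must be positive",
                 class = "diffpop_validation_error")
  }
  check_number(a$dose, "dose_iv", min = 0, allow_min = FALSE)
  check_number(b$dose, "dose_ev", min = 0, allow_min = FALSE)
  100 * (b$auc / b$dose) / (a$auc / a$dose)
}

#' Total time a concentration profile spends above a threshold
#'
#' Sums the duration over which the interpolated profile exceeds the
#' threshold. Crossing times between bracketing points are located by
#' log-linear interpolation (concentrations decay exponentially between
#' samples); a linear fallback is used if a bracketing concentration is
#' non-positive.
#'
#' @param times Strictly increasing times (h).
#' @param conc Concentrations (no missing values).
#' @param threshold Positive concentration threshold.
#'
#' @return Time above threshold, in the unit of `times`.
#' @examples
#' time_above_threshold(c(0, 4), c(2, 0.5), threshold = 1)
#' @export
time_above_threshold <- function(times, conc, threshold = 1) {
  check_profile_vectors(times, conc)
  check_number(threshold, "threshold", min = 0, allow_min = FALSE)
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- times[i]; t2 <- times[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    above1 <- c1 > threshold
    above2 <- c2 > threshold
    if (above1 && above2) {
      total <- total + (t2 - t1)
    } else if (above1 != above2) {
      t_cross <- if (c1 > 0 && c2 > 0 && c1 != c2) {
        t1 + (t2 - t1) * log(c1 / threshold) / log(c1 / c2)
      } else {
        t1 + (t2 - t1) * (c1 - threshold) / (c1 - c2)
      }
      total <- total + if (above1) t_cross - t1 else t2 - t_cross
    }
  }
  total
}

check_profile_vectors <- function(times, conc) {
  if (!is.numeric(times) || !is.numeric(conc) ||
      length(times) != length(conc) || length(times) < 2L ||
      anyNA(times) || anyNA(conc)) {
    stop_diffpop(
      "`times` and `conc` must be equal-length numeric vectors (>= 2) without missing values",
      class = "diffpop_validation_error"
    )
  }
  if (any(diff(times) <= 0)) {
    stop_diffpop("`times` must be strictly increasing",
                 class = "diffpop_validation_error")
  }
  invisible(TRUE)
}
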
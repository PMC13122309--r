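#' Simulate a one-compartment plasma concentration-time profile
#'
#' IV bolus profiles follow `C(t) = (dose / volume) * exp(-k t)`; profiles
#' with first-order absorption (e.g. intraperitoneal dosing) follow the
#' Bateman form with complete absorption,
#' `C(t) = (dose / volume) * ka / (ka - k) * (exp(-k t) - exp(-ka t))`.
#' Concentrations below the lower limit of quantification are flagged, not
#' removed, so downstream analysis owns the exclusion rule.
#'
#' The default sampling times are the serial bleeds of the murine study
#' (5 min to 24 h).
#'
#' @param dose Administered dose per kg body weight.
#' @param volume Distribution volume per kg (same mass/volume unit system
#'   as `dose`, so `dose / volume` is a concentration).
#' @param elimination_rate First-order elimination rate constant `k`
#'   (1/h, > 0).
#' @param absorption_rate First-order absorption rate constant `ka` (1/h);
#'   `NULL` (default) simulates an IV bolus. `ka == k` is degenerate and
#'   rejected.
#' @param times Sampling times in hours, strictly increasing, >= 0.
#' @param lloq Lower limit of quantification; concentrations below it are
#'   flagged `below_lloq = TRUE`.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   assay noise (0 disables).
#' @param seed Integer seed (only consulted when `noise_cv > 0`).
#'
#' @return A tibble with `time_h`, `conc`, `below_lloq`.
#' @examples
#' simulate_pk_profile(dose = 1, volume = 0.1, elimination_rate = log(2))
#' @export
simulate_pk_profile <- function(dose, volume, elimination_rate,
                                absorption_rate = NULL,
                                times = c(0.083, 0.25, 0.5, 1, 2, 4, 8, 24),
                                lloq = 0, noise_cv = 0, seed = 1L) {
  check_number(dose, "dose", min = 0, allow_min = FALSE)
  check_number(volume, "volume", min = 0, allow_min = FALSE)
  check_number(elimination_rate, "elimination_rate", min = 0,
               allow_min = FALSE)
  check_number(lloq, "lloq", min = 0)
  check_number(noise_cv, "noise_cv", min = 0)
  if (!is.numeric(times) || length(times) < 2L || anyNA(times) ||
      any(times < 0) || any(diff(times) <= 0)) {
    stop_diffpop("`times` must be non-negative and strictly increasing",
                 class = "diffpop_validation_error")
  }
  k <- elimination_rate
  c0 <- dose / volume
  if (is.null(absorption_rate)) {
    conc <- c0 * exp(-k * times)
  } else {
    ka <- check_number(absorption_rate, "absorption_rate", min = 0,
                       allow_min = FALSE)
    if (isTRUE(all.equal(ka, k))) {
      stop_diffpop(
        "`absorption_rate` equal to `elimination_rate` is degenerate",
        class = "diffpop_validation_error"
      )
    }
    conc <- c0 * ka / (ka - k) * (exp(-k * times) - exp(-ka * times))
  }
  if (noise_cv > 0) {
    conc <- withr::with_seed(
      seed, conc * lognormal_noise(length(conc), noise_cv)
    )
  }
  tibble(time_h = times, conc = conc, below_lloq = conc < lloq)
}

#' Simulate four-parameter logistic dose-viability data
#'
#' Viability is generated from the standard 4PL model
#' `bottom + (top - bottom) / (1 + (dose / ic50)^hill)` with optional
#' additive Gaussian noise, emulating plate-reader viability normalized to
#' vehicle (%).
#'
#' @param ic50 Dose at half-effect (> 0, same unit as `doses`).
#' @param hill Slope factor; positive for viability falling with dose.
#' @param top,bottom Upper and lower response asymptotes (%).
#' @param doses Dose levels (> 0); each measured `n_replicates` times.
#' @param n_replicates Replicates per dose.
#' @param sd Additive response noise SD (response units).
#' @param seed Integer seed (consulted when `sd > 0`).
#'
#' @return A tibble with `dose`, `replicate`, `response`.
#' @examples
#' simulate_dose_response(ic50 = 1.31, doses = 10^seq(-2, 2, length.out = 8))
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   doses = 10^seq(-2, 2, length.out = 10),
                                   n_replicates = 3, sd = 0, seed = 1L) {
  check_number(ic50, "ic50", min = 0, allow_min = FALSE)
  check_number(sd, "sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  if (!is.numeric(doses) || any(doses <= 0)) {
    stop_diffpop("`doses` must be positive", class = "diffpop_validation_error")
  }
  out <- tidyr::expand_grid(dose = sort(doses),
                            replicate = seq_len(n_replicates))
  mu <- bottom + (top - bottom) / (1 + (out$dose / ic50)^hill)
  out$response <- if (sd > 0) {
    withr::with_seed(seed, mu + rnorm(nrow(out), 0, sd))
  } else {
    mu
  }
  out
}
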
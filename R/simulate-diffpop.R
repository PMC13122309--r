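#' Expected per-fraction intensities from a logistic precipitation curve
#'
#' Models cumulative precipitation of one protein along the solvent ladder
#' as a logistic function of solvent concentration: a protein with midpoint
#' `m` is half-precipitated at `m`% solvent, and fraction `j` captures the
#' probability mass accumulated between the previous step's concentration
#' and its own. Ligand binding that stabilizes the folded state delays
#' precipitation, which is modelled as a rightward displacement of the
#' midpoint by `shift_delta` solvent points.
#'
#' The cumulative curve is evaluated at a notional 0% baseline for the
#' first fraction (not forced to zero), so mass precipitated "before" the
#' first step, or beyond the last step, is simply not captured; the summed
#' fraction intensities are therefore at most `abundance` and approach it
#' as the ladder covers the curve.
#'
#' @param midpoint Solvent % (v/v) at which half the protein has
#'   precipitated. Should lie within the design's concentration range.
#' @param steepness Positive slope of the logistic curve (per solvent
#'   point).
#' @param abundance Total protein intensity (arbitrary units, > 0).
#' @param design A [fractionation_design()] tibble or a numeric ladder.
#' @param shift_delta Displacement of the midpoint under compound
#'   treatment, in solvent points; positive means stabilized (delayed
#'   precipitation).
#' @param shifted If `TRUE`, apply `shift_delta` to the midpoint (the
#'   compound condition); if `FALSE`, simulate the vehicle condition.
#'
#' @return A tibble with `fraction_index`, `methanol_pct`, and the
#'   noise-free expected `intensity` per fraction.
#' @examples
#' precipitation_profile(midpoint = 25, steepness = 0.3, abundance = 100)
#' @export
precipitation_profile <- function(midpoint, steepness, abundance = 1,
                                  design = fractionation_design(),
                                  shift_delta = 0, shifted = FALSE) {
  design <- as_fractionation_design(design)
  check_number(midpoint, "midpoint", min = 0, max = 100)
  check_number(steepness, "steepness", min = 0, allow_min = FALSE)
  check_number(abundance, "abundance", min = 0, allow_min = FALSE)
  check_number(shift_delta, "shift_delta")
  m <- midpoint + if (isTRUE(shifted)) shift_delta else 0
  cdf <- plogis(steepness * (c(0, design$methanol_pct) - m))
  design$intensity <- abundance * diff(cdf)
  design
}

#' Simulate a full DiffPOP experiment with planted stabilized targets
#'
#' Generates the long-format protein-by-fraction intensity table the shift
#' analysis consumes: `n_proteins` proteins, two conditions (`"vehicle"`
#' and `"compound"`), `n_replicates` replicates per condition, and one row
#' per fraction of the design. A random subset of `n_targets` proteins is
#' planted as compound-stabilized: their logistic precipitation midpoint is
#' displaced by `shift_delta` solvent points under compound. All other
#' proteins have identical expected profiles in both conditions.
#'
#' Noise is multiplicative lognormal with coefficient of variation
#' `noise_cv` (mean-one, so expected intensities are preserved); values
#' falling below `dropout_threshold` are recorded missing, mimicking
#' low-abundance missingness in MS data.
#'
#' @param n_proteins Number of proteins.
#' @param n_targets Number of planted stabilized targets
#'   (`<= n_proteins`).
#' @param n_replicates Replicates per condition (>= 2; the study used
#'   triplicates).
#' @param design A [fractionation_design()] tibble or numeric ladder.
#' @param shift_delta Midpoint displacement for planted targets, solvent
#'   points.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 disables noise).
#' @param dropout_threshold Intensity below which a value is recorded
#'   missing (0 disables dropout).
#' @param midpoint_range,steepness_range Per-protein sampling ranges for
#'   the precipitation-curve parameters.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters for total
#'   protein abundance.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   output exactly.
#'
#' @return A list with `data` (long tibble: `protein_id`, `condition`,
#'   `replicate`, `fraction_index`, `methanol_pct`, `intensity`,
#'   `is_missing`) and `truth` (tibble: `protein_id`, `is_target`,
#'   `shift_delta`, `midpoint`, `steepness`, `abundance`).
#' @examples
#' sim <- simulate_diffpop(n_proteins = 20, n_targets = 2, seed = 1)
#' head(sim$data)
#' @export
simulate_diffpop <- function(n_proteins = 300, n_targets = 5,
                             n_replicates = 3,
                             design = fractionation_design(),
                             shift_delta = 15, noise_cv = 0.1,
                             dropout_threshold = 0,
                             midpoint_range = c(10, 60),
                             steepness_range = c(0.15, 0.5),
                             abundance_meanlog = log(1e6),
                             abundance_sdlog = 1,
                             seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  n_targets <- check_count(n_targets, "n_targets", min = 0L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  if (n_targets > n_proteins) {
    stop_diffpop("`n_targets` must not exceed `n_proteins`",
                 class = "diffpop_validation_error")
  }
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(dropout_threshold, "dropout_threshold", min = 0)
  design <- as_fractionation_design(design)

  withr::with_seed(seed, {
    ids <- protein_ids(n_proteins)
    target_ids <- if (n_targets > 0) sample(ids, n_targets) else character()
    truth <- tibble(
      protein_id = ids,
      is_target = ids %in% target_ids,
      shift_delta = ifelse(ids %in% target_ids, shift_delta, 0),
      midpoint = runif(n_proteins, midpoint_range[1], midpoint_range[2]),
      steepness = runif(n_proteins, steepness_range[1], steepness_range[2]),
      abundance = rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
    )

    grid <- tidyr::expand_grid(
      protein_id = ids,
      condition = c("vehicle", "compound"),
      replicate = seq_len(n_replicates),
      design
    )
    grid <- dplyr::left_join(grid, truth, by = "protein_id")
    mid <- grid$midpoint +
      ifelse(grid$condition == "compound" & grid$is_target,
             grid$shift_delta, 0)
    cdf_hi <- plogis(grid$steepness * (grid$methanol_pct - mid))
    prev_pct <- c(0, design$methanol_pct)[grid$fraction_index]
    cdf_lo <- plogis(grid$steepness * (prev_pct - mid))
    expected <- grid$abundance * (cdf_hi - cdf_lo)
    intensity <- expected * lognormal_noise(length(expected), noise_cv)
    is_missing <- intensity < dropout_threshold
    data <- tibble(
      protein_id = grid$protein_id,
      condition = grid$condition,
      replicate = grid$replicate,
      fraction_index = grid$fraction_index,
      methanol_pct = grid$methanol_pct,
      intensity = ifelse(is_missing, NA_real_, intensity),
      is_missing = is_missing
    )
    list(data = data, truth = truth)
  })
}
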
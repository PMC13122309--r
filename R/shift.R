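#' Normalize a precipitation profile to per-fraction shares
#'
#' Converts raw per-fraction intensities of one protein into shares that
#' sum to one, so profiles are comparable across proteins and conditions
#' regardless of total abundance (the normalized spectral-abundance style
#' scaling used in precipitation profiling). Missing values default to
#' zero: an absent pellet value is read as no protein precipitating at
#' that step.
#'
#' @param intensities Non-negative per-fraction intensities; `NA` allowed.
#' @param missing_policy `"zero"` (default) replaces missing values with
#'   0; `"error"` refuses profiles containing missing values.
#'
#' @return Numeric vector of shares summing to 1.
#' @examples
#' normalize_profile(c(2, 6, 2, 0, 0, 0, 0, 0, 0))
#' @export
normalize_profile <- function(intensities,
                              missing_policy = c("zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.numeric(intensities) || length(intensities) < 1L) {
    stop_diffpop("`intensities` must be a numeric vector",
                 class = "diffpop_validation_error")
  }
  if (anyNA(intensities)) {
    if (missing_policy == "error") {
      stop_diffpop("profile contains missing values",
                   class = "diffpop_unscorable")
    }
    intensities[is.na(intensities)] <- 0
  }
  if (any(intensities < 0)) {
    stop_diffpop("intensities must be non-negative",
                 class = "diffpop_validation_error")
  }
  total <- sum(intensities)
  if (total <= 0) {
    stop_diffpop("profile has no positive intensity; protein is unscorable",
                 class = "diffpop_unscorable")
  }
  intensities / total
}

#' Kolmogorov-Smirnov shift statistic between two fraction profiles
#'
#' The shift statistic D is the maximum absolute difference between the
#' cumulative normalized precipitation profiles of two conditions across
#' the ordered fractions. It is 0 when the cumulative profiles coincide
#' and 1 when all mass precipitates in disjoint, fully separated parts of
#' the ladder; a ligand-stabilized target shows a large D because its
#' precipitation is delayed to later fractions.
#'
#' @param profile_a,profile_b Normalized profiles (shares summing to 1) of
#'   equal length over the same design.
#'
#' @return D in [0, 1].
#' @examples
#' ks_shift_statistic(c(0.5, 0.5, 0, 0), c(0, 0.5, 0.5, 0))
#' @export
ks_shift_statistic <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop_diffpop("profiles must have the same number of fractions",
                 class = "diffpop_validation_error")
  }
  for (p in list(profile_a, profile_b)) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      stop_diffpop("profiles must be normalized shares summing to 1",
                   class = "diffpop_validation_error")
    }
  }
  d <- max(abs(cumsum(profile_a) - cumsum(profile_b)))
  min(max(d, 0), 1)
}

#' Direction and location summary of a precipitation shift
#'
#' Computes intensity-weighted centroids of both profiles in solvent
#' percent, their difference (compound minus vehicle), and the 1-based
#' peak (argmax) fraction of each profile, with ties broken toward the
#' lowest fraction. A positive centroid shift means the compound profile
#' sits at higher solvent concentrations, i.e. the protein is stabilized
#' (delayed precipitation).
#'
#' @param profile_vehicle,profile_compound Normalized profiles.
#' @param design A [fractionation_design()] tibble or numeric ladder.
#'
#' @return One-row tibble: `centroid_vehicle`, `centroid_compound`,
#'   `centroid_shift`, `peak_vehicle`, `peak_compound`, `stabilized`.
#' @examples
#' d <- fractionation_design()
#' shift_direction(c(0, 1, rep(0, 7)), c(0, 0, 1, rep(0, 6)), d)
#' @export
shift_direction <- function(profile_vehicle, profile_compound,
                            design = fractionation_design()) {
  design <- as_fractionation_design(design)
  n <- nrow(design)
  if (length(profile_vehicle) != n || length(profile_compound) != n) {
    stop_diffpop("profiles must match the design length",
                 class = "diffpop_validation_error")
  }
  centroid <- function(p) sum(p * design$methanol_pct)
  cv <- centroid(profile_vehicle)
  cc <- centroid(profile_compound)
  tibble(
    centroid_vehicle = cv,
    centroid_compound = cc,
    centroid_shift = cc - cv,
    peak_vehicle = which.max(profile_vehicle),
    peak_compound = which.max(profile_compound),
    stabilized = (cc - cv) > 0
  )
}

#' Minimum pairwise replicate Spearman correlation
#'
#' Technical reproducibility gate for one protein in one condition: the
#' Spearman rank correlation (average ranks for ties) is computed on the
#' raw per-fraction intensities of every unordered replicate pair, and the
#' minimum is returned. A replicate with zero variance across fractions
#' makes the correlation undefined for its pairs; `NA` is returned so the
#' protein fails any finite gate.
#'
#' @param profiles Numeric matrix or data frame with fractions in rows and
#'   replicates in columns (>= 2 replicates). Missing values are treated
#'   as zero intensity.
#'
#' @return Minimum pairwise Spearman rho, or `NA` if any pair is
#'   undefined.
#' @examples
#' replicate_reproducibility(cbind(1:9, c(1:8, 10)))
#' @export
replicate_reproducibility <- function(profiles) {
  m <- as.matrix(profiles)
  if (!is.numeric(m) || ncol(m) < 2L) {
    stop_diffpop("need a numeric matrix with >= 2 replicate columns",
                 class = "diffpop_validation_error")
  }
  m[is.na(m)] <- 0
  rho <- suppressWarnings(cor(m, method = "spearman"))
  pairs <- rho[upper.tri(rho)]
  if (anyNA(pairs)) return(NA_real_)
  min(pairs)
}

#' Permutation p-value for a protein's shift statistic
#'
#' Optional diagnostic: under the null of no compound effect, condition
#' labels are exchangeable across a protein's replicates. The observed D
#' (computed between mean normalized condition profiles) is compared with
#' its distribution over relabelings of the replicates. All distinct
#' labelings are enumerated when there are at most `max_exact` of them;
#' otherwise `n_perm` random relabelings are drawn. Note this resolution
#' is coarse with 3 + 3 replicates (20 labelings), which is why the
#' pipeline's operative significance rule is the quantile rule, not this
#' p-value.
#'
#' @param profiles Matrix of raw replicate profiles, fractions in rows.
#' @param conditions Character vector (one per column) with two levels.
#' @param n_perm Random permutations when exact enumeration is infeasible.
#' @param max_exact Enumeration limit on distinct labelings.
#' @param seed Seed for the random fallback.
#'
#' @return List with `d_observed` and `p_value`.
#' @examples
#' m <- cbind(c(5, 1, 0), c(4, 2, 0), c(0, 1, 5), c(0, 2, 4))
#' ks_permutation_pvalue(m, c("vehicle", "vehicle", "compound", "compound"))
#' @export
ks_permutation_pvalue <- function(profiles, conditions, n_perm = 999,
                                  max_exact = 1000, seed = 1L) {
  m <- as.matrix(profiles)
  if (ncol(m) != length(conditions)) {
    stop_diffpop("`conditions` must label every replicate column",
                 class = "diffpop_validation_error")
  }
  lev <- unique(conditions)
  if (length(lev) != 2L) {
    stop_diffpop("exactly two condition levels required",
                 class = "diffpop_validation_error")
  }
  norm_mean <- function(cols) {
    shares <- apply(m[, cols, drop = FALSE], 2, normalize_profile)
    rowMeans(shares)
  }
  d_for <- function(idx_a) {
    idx_b <- setdiff(seq_len(ncol(m)), idx_a)
    ks_shift_statistic(norm_mean(idx_a), norm_mean(idx_b))
  }
  obs_idx <- which(conditions == lev[1])
  d_obs <- d_for(obs_idx)
  k <- length(obs_idx)
  if (choose(ncol(m), k) <= max_exact) {
    all_idx <- combn(ncol(m), k, simplify = FALSE)
    d_null <- vapply(all_idx, d_for, numeric(1))
    p <- mean(d_null >= d_obs - 1e-12)
  } else {
    d_null <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        d_for(sample(ncol(m), k))
      }, numeric(1))
    })
    p <- (1 + sum(d_null >= d_obs - 1e-12)) / (n_perm + 1)
  }
  list(d_observed = d_obs, p_value = p)
}
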
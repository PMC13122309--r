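#' Score stabilization shifts for every protein in a DiffPOP dataset
#'
#' For each protein, replicate profiles are checked for technical
#' reproducibility (minimum pairwise Spearman rho within each condition);
#' proteins passing the gate in both conditions have their normalized
#' replicate profiles averaged into one profile per condition, on which
#' the Kolmogorov-Smirnov shift statistic, centroid shift and peak
#' fractions are computed. Proteins failing the gate are still summarized
#' but flagged and excluded from ranking; proteins missing a condition or
#' with no positive intensity are unscorable.
#'
#' @param data Long-format tibble with columns `protein_id`, `condition`
#'   (`"vehicle"` / `"compound"`), `replicate`, `fraction_index`,
#'   `intensity`, and optionally `is_missing` and `methanol_pct`.
#' @param design A [fractionation_design()] tibble or numeric ladder;
#'   if `NULL`, recovered from the data's `fraction_index` /
#'   `methanol_pct` columns.
#' @param spearman_gate Reproducibility threshold; a protein is ranked
#'   only if its minimum pairwise replicate correlation exceeds this in
#'   both conditions.
#' @param replicate_ds If `TRUE`, add diagnostic columns with the mean and
#'   range of the per-replicate-pair shift statistics (every vehicle
#'   replicate against every compound replicate).
#'
#' @return A tibble with one row per protein: `protein_id`, `ks_stat`,
#'   `centroid_vehicle`, `centroid_compound`, `centroid_shift`,
#'   `peak_vehicle`, `peak_compound`, `min_spearman`, `passed_gate`,
#'   `scored`, `reason`.
#' @examples
#' sim <- simulate_diffpop(n_proteins = 20, n_targets = 2, noise_cv = 0,
#'                         seed = 1)
#' score_shifts(sim$data)
#' @export
score_shifts <- function(data, design = NULL, spearman_gate = 0.7,
                         replicate_ds = FALSE) {
  required <- c("protein_id", "condition", "replicate", "fraction_index",
                "intensity")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_diffpop(paste0("missing required columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "diffpop_schema_error")
  }
  check_number(spearman_gate, "spearman_gate", min = -1, max = 1)
  if (is.null(design)) {
    if (!"methanol_pct" %in% names(data)) {
      stop_diffpop(
        "supply `design` or include a `methanol_pct` column in the data",
        class = "diffpop_schema_error"
      )
    }
    design <- dplyr::distinct(data, .data$fraction_index,
                              .data$methanol_pct)
    design <- as_fractionation_design(design)
  } else {
    design <- as_fractionation_design(design)
  }
  n_frac <- nrow(design)
  if (!all(data$fraction_index %in% design$fraction_index)) {
    stop_diffpop("data contains fraction indices outside the design",
                 class = "diffpop_schema_error")
  }
  intensity <- data$intensity
  if ("is_missing" %in% names(data)) {
    intensity[which(data$is_missing)] <- NA_real_
  }
  work <- tibble(
    protein_id = data$protein_id,
    condition = data$condition,
    replicate = data$replicate,
    fraction_index = data$fraction_index,
    intensity = intensity
  )

  score_one <- function(sub) {
    out <- tibble(
      protein_id = sub$protein_id[1],
      ks_stat = NA_real_, centroid_vehicle = NA_real_,
      centroid_compound = NA_real_, centroid_shift = NA_real_,
      peak_vehicle = NA_integer_, peak_compound = NA_integer_,
      min_spearman = NA_real_, passed_gate = FALSE, scored = FALSE,
      reason = NA_character_
    )
    if (replicate_ds) {
      out$d_pair_mean <- NA_real_
      out$d_pair_min <- NA_real_
      out$d_pair_max <- NA_real_
    }
    conds <- unique(sub$condition)
    if (!all(c("vehicle", "compound") %in% conds)) {
      out$reason <- "missing_condition"
      return(out)
    }
    mats <- lapply(c("vehicle", "compound"), function(cond) {
      s <- sub[sub$condition == cond, ]
      reps <- sort(unique(s$replicate))
      m <- matrix(NA_real_, nrow = n_frac, ncol = length(reps),
                  dimnames = list(NULL, reps))
      m[cbind(s$fraction_index, match(s$replicate, reps))] <- s$intensity
      m[is.na(m)] <- 0
      m
    })
    names(mats) <- c("vehicle", "compound")
    if (any(vapply(mats, function(m) any(colSums(m) <= 0), logical(1)))) {
      out$reason <- "empty_profile"
      return(out)
    }
    ms <- vapply(mats, replicate_reproducibility, numeric(1))
    out$min_spearman <- if (anyNA(ms)) NA_real_ else min(ms)
    out$passed_gate <- !anyNA(ms) && all(ms > spearman_gate)
    shares <- lapply(mats, function(m) apply(m, 2, normalize_profile))
    mean_profiles <- lapply(shares, rowMeans)
    out$ks_stat <- ks_shift_statistic(mean_profiles$vehicle,
                                      mean_profiles$compound)
    dir <- shift_direction(mean_profiles$vehicle, mean_profiles$compound,
                           design)
    out$centroid_vehicle <- dir$centroid_vehicle
    out$centroid_compound <- dir$centroid_compound
    out$centroid_shift <- dir$centroid_shift
    out$peak_vehicle <- dir$peak_vehicle
    out$peak_compound <- dir$peak_compound
    out$scored <- out$passed_gate
    if (!out$passed_gate) out$reason <- "failed_spearman_gate"
    if (replicate_ds) {
      pair_d <- as.vector(vapply(
        seq_len(ncol(shares$vehicle)),
        function(i) {
          vapply(seq_len(ncol(shares$compound)), function(j) {
            ks_shift_statistic(shares$vehicle[, i], shares$compound[, j])
          }, numeric(1))
        },
        numeric(ncol(shares$compound))
      ))
      out$d_pair_mean <- mean(pair_d)
      out$d_pair_min <- min(pair_d)
      out$d_pair_max <- max(pair_d)
    }
    out
  }

  split_data <- split(work, work$protein_id)
  res <- dplyr::bind_rows(lapply(split_data, score_one))
  dplyr::arrange(res, .data$protein_id)
}

#' Call candidate targets with the top-quantile significance rule
#'
#' Scored proteins are ranked by the shift statistic D (descending; ties
#' broken by larger centroid shift, then protein ID), and the top
#' `ceiling(quantile * N_scored)` proteins pass the rank cut. With nine
#' fractions the asymptotic KS null is unusable, so this fixed top-3%
#' quantile is the operative significance rule. Candidates are then
#' optionally restricted to stabilized proteins (positive centroid shift,
#' i.e. precipitation delayed to higher solvent concentrations under
#' compound).
#'
#' @param results Output of [score_shifts()].
#' @param quantile Fraction of scored proteins passing the rank cut, in
#'   (0, 1].
#' @param require_stabilized If `TRUE` (default), keep only candidates
#'   with positive centroid shift.
#' @param .keep_all If `TRUE`, return every row of `results` annotated
#'   with `quantile_rank` and `is_candidate` instead of the candidate
#'   subset.
#'
#' @return Candidate tibble sorted by D descending (or the annotated full
#'   table when `.keep_all = TRUE`), with columns `quantile_rank` and
#'   `is_candidate` added.
#' @examples
#' sim <- simulate_diffpop(n_proteins = 50, n_targets = 2, noise_cv = 0,
#'                         seed = 1)
#' call_targets(score_shifts(sim$data))
#' @export
call_targets <- function(results, quantile = 0.03,
                         require_stabilized = TRUE, .keep_all = FALSE) {
  check_number(quantile, "quantile", min = 0, max = 1, allow_min = FALSE)
  if (!all(c("protein_id", "ks_stat", "centroid_shift", "scored")
           %in% names(results))) {
    stop_diffpop("`results` must come from score_shifts()",
                 class = "diffpop_validation_error")
  }
  scored <- dplyr::filter(results, .data$scored)
  if (nrow(scored) == 0) {
    stop_diffpop("no scored proteins to rank",
                 class = "diffpop_validation_error")
  }
  scored <- dplyr::arrange(scored, dplyr::desc(.data$ks_stat),
                           dplyr::desc(.data$centroid_shift),
                           .data$protein_id)
  scored$quantile_rank <- seq_len(nrow(scored))
  n_top <- ceiling(quantile * nrow(scored))
  scored$is_candidate <- scored$quantile_rank <= n_top &
    (!require_stabilized | scored$centroid_shift > 0)
  if (.keep_all) {
    unscored <- dplyr::filter(results, !.data$scored)
    if (nrow(unscored) > 0) {
      unscored$quantile_rank <- NA_integer_
      unscored$is_candidate <- FALSE
      scored <- dplyr::bind_rows(scored, unscored)
    }
    return(scored)
  }
  dplyr::filter(scored, .data$is_candidate)
}
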
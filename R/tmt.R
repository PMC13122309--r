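#' Impute missing TMT reporter values with the protein's lowest observed
#' intensity
#'
#' Missing reporter-ion values are replaced by the minimum observed
#' intensity across that protein's six channels, the conservative fill
#' that lets every quantified protein enter the fold-change calculation
#' without inventing signal above what was seen. Observed values are
#' never altered. Proteins missing in all channels cannot be imputed and
#' are dropped, with their IDs recorded in the `"dropped_proteins"`
#' attribute.
#'
#' @param matrix Reporter matrix: tibble with `protein_id` plus one column
#'   per channel.
#' @param channel_map Channel assignment, see [tmt_channel_map()].
#'
#' @return The matrix with no missing channel values.
#' @examples
#' m <- tibble::tibble(protein_id = "P1", `126.1` = 5, `127.1` = NA,
#'                     `128.1` = 7, `129.1` = 8, `130.1` = 6, `131.1` = 9)
#' impute_missing_tmt(m)
#' @export
impute_missing_tmt <- function(matrix, channel_map = tmt_channel_map()) {
  validate_channel_map(channel_map)
  channels <- channel_map$channel
  check_reporter_matrix(matrix, channels)
  m <- as.matrix(matrix[, channels])
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    inform(sprintf(
      "dropping %d protein(s) with no observed reporter value",
      sum(all_missing)
    ))
  }
  dropped <- matrix$protein_id[all_missing]
  matrix <- matrix[!all_missing, , drop = FALSE]
  m <- m[!all_missing, , drop = FALSE]
  row_min <- apply(m, 1, min, na.rm = TRUE)
  for (ch in channels) {
    v <- matrix[[ch]]
    v[is.na(v)] <- row_min[is.na(v)]
    matrix[[ch]] <- v
  }
  attr(matrix, "dropped_proteins") <- dropped
  matrix
}

#' Normalize a TMT reporter matrix (log2, median centering, variance
#' scaling)
#'
#' Intensities are log2-transformed, then each channel is median-centered
#' and scaled to unit spread, removing channel-loading and labeling-
#' efficiency differences before differential testing. After the step
#' every channel has median 0 and (with the default estimator) standard
#' deviation 1.
#'
#' @param matrix Reporter matrix with strictly positive intensities (run
#'   [impute_missing_tmt()] first if values are missing).
#' @param channel_map Channel assignment, see [tmt_channel_map()].
#' @param scale_estimator `"sd"` (default) scales each channel by its
#'   standard deviation; `"mad"` uses the median absolute deviation
#'   (consistency-scaled).
#'
#' @return The matrix with channel values on the normalized log2 scale.
#' @examples
#' sim <- simulate_tmt(n_proteins = 50, missing_rate = 0, seed = 1)
#' normalize_tmt(sim$matrix)
#' @export
normalize_tmt <- function(matrix, channel_map = tmt_channel_map(),
                          scale_estimator = c("sd", "mad")) {
  scale_estimator <- match.arg(scale_estimator)
  validate_channel_map(channel_map)
  channels <- channel_map$channel
  check_reporter_matrix(matrix, channels)
  for (ch in channels) {
    v <- matrix[[ch]]
    if (anyNA(v) || any(v <= 0)) {
      stop_diffpop(
        "intensities must be strictly positive and complete; impute first",
        class = "diffpop_validation_error"
      )
    }
    x <- log2(v)
    x <- x - median(x)
    s <- if (scale_estimator == "sd") sd(x) else mad(x)
    if (!is.finite(s) || s == 0) {
      stop_diffpop(sprintf("channel %s has zero spread", ch),
                   class = "diffpop_validation_error")
    }
    matrix[[ch]] <- x / s
  }
  matrix
}

#' Per-protein differential abundance test on a reporter matrix
#'
#' Computes the log2 fold change (mean compound minus mean vehicle on the
#' log2 scale) and a two-sided two-sample t-type p-value per protein. For
#' the balanced TMT 3-vs-3 design the equal-variance (pooled) test is the
#' default. P-values are reported raw, with no multiplicity adjustment.
#' Proteins with zero spread in both groups get p = 1 when the group
#' means agree (no evidence) and p = 0, flagged `degenerate`, when they
#' differ (the test's limiting value on noise-free data).
#'
#' @param matrix Reporter matrix (tibble: `protein_id` + channel columns).
#' @param channel_map Channel assignment, see [tmt_channel_map()].
#' @param transform `"log2"` (default) when the matrix holds raw
#'   intensities; `"identity"` when values are already on a log2-like
#'   scale (e.g. after [normalize_tmt()]).
#' @param var_equal Pooled-variance test if `TRUE` (default for balanced
#'   TMT), Welch otherwise.
#'
#' @return Tibble with `protein_id`, `log2fc`, `t_stat`, `df`, `p_raw`,
#'   `degenerate`.
#' @examples
#' sim <- simulate_tmt(n_proteins = 50, missing_rate = 0, seed = 1)
#' differential_test(sim$matrix)
#' @export
differential_test <- function(matrix, channel_map = tmt_channel_map(),
                              transform = c("log2", "identity"),
                              var_equal = TRUE) {
  transform <- match.arg(transform)
  validate_channel_map(channel_map)
  channels <- channel_map$channel
  check_reporter_matrix(matrix, channels)
  m <- as.matrix(matrix[, channels])
  if (transform == "log2") {
    if (any(m <= 0, na.rm = TRUE)) {
      stop_diffpop("raw intensities must be positive for log2 transform",
                   class = "diffpop_validation_error")
    }
    m <- log2(m)
  }
  veh <- m[, channel_map$channel[channel_map$condition == "vehicle"],
           drop = FALSE]
  cmp <- m[, channel_map$channel[channel_map$condition == "compound"],
           drop = FALSE]
  res <- row_t_test(veh, cmp, var_equal = var_equal)
  tibble(
    protein_id = matrix$protein_id,
    log2fc = res$estimate,
    t_stat = res$t_stat,
    df = res$df,
    p_raw = res$p_raw,
    degenerate = res$degenerate
  )
}

#' Classify differential results against volcano cutoffs
#'
#' A protein is called `"up"` when its log2 fold change is at least
#' `fc_cut` and its raw p-value is below `p_cut`; `"down"` when the fold
#' change is at most `-fc_cut` with the same p criterion; otherwise
#' `"ns"`. The default fold-change cutoff of 0.38 on the log2 scale
#' corresponds to roughly a 30% change in abundance.
#'
#' @param results Tibble with `log2fc` and `p_raw` (from
#'   [differential_test()] or [dia_differential()]).
#' @param p_cut Raw p-value threshold (strict `<`).
#' @param fc_cut Absolute log2 fold-change threshold (inclusive `>=`).
#'
#' @return `results` with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @examples
#' volcano_call(tibble::tibble(protein_id = "P1", log2fc = 0.5,
#'                             p_raw = 0.01))
#' @export
volcano_call <- function(results, p_cut = 0.05, fc_cut = 0.38) {
  check_number(p_cut, "p_cut", min = 0, max = 1, allow_min = FALSE)
  check_number(fc_cut, "fc_cut", min = 0)
  if (!all(c("log2fc", "p_raw") %in% names(results))) {
    stop_diffpop("`results` must contain log2fc and p_raw",
                 class = "diffpop_validation_error")
  }
  results$call <- dplyr::case_when(
    results$p_raw < p_cut & results$log2fc >= fc_cut ~ "up",
    results$p_raw < p_cut & results$log2fc <= -fc_cut ~ "down",
    .default = "ns"
  )
  results
}

check_reporter_matrix <- function(matrix, channels) {
  if (!is.data.frame(matrix) || !"protein_id" %in% names(matrix)) {
    stop_diffpop("reporter matrix needs a `protein_id` column",
                 class = "diffpop_schema_error")
  }
  missing_ch <- setdiff(channels, names(matrix))
  if (length(missing_ch) > 0) {
    stop_diffpop(paste0("reporter matrix is missing channel column(s): ",
                        paste(missing_ch, collapse = ", ")),
                 class = "diffpop_schema_error")
  }
  if (anyDuplicated(matrix$protein_id)) {
    stop_diffpop("duplicate protein IDs in reporter matrix",
                 class = "diffpop_schema_error")
  }
  invisible(matrix)
}
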
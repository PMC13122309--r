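#' Fractionation design for a sequential precipitation experiment
#'
#' A DiffPOP experiment precipitates protein from a single lysate by adding
#' increasing amounts of acidified methanol and pelleting after each
#' addition, so each fraction is indexed by the final solvent concentration
#' reached at that step. The default ladder is the nine-step acidified
#' methanol gradient used in the OVCAR3 target-deconvolution study.
#'
#' @param methanol_pct Strictly increasing final solvent concentrations
#'   (% v/v), one per fraction, all in (0, 100).
#'
#' @return A tibble with columns `fraction_index` (1-based) and
#'   `methanol_pct`.
#' @examples
#' fractionation_design()
#' fractionation_design(c(10, 30, 50, 70, 90))
#' @export
fractionation_design <- function(methanol_pct = c(2.62, 6.45, 11.98, 19.80,
                                                  30.53, 44.53, 61.38, 79.03,
                                                  87.50)) {
  if (!is.numeric(methanol_pct) || length(methanol_pct) < 2L ||
      anyNA(methanol_pct)) {
    stop_diffpop("`methanol_pct` must be a numeric vector of length >= 2",
                 class = "diffpop_validation_error")
  }
  if (any(diff(methanol_pct) <= 0)) {
    stop_diffpop("fraction concentrations must be strictly increasing",
                 class = "diffpop_validation_error")
  }
  if (any(methanol_pct <= 0 | methanol_pct >= 100)) {
    stop_diffpop("fraction concentrations must lie in (0, 100) % v/v",
                 class = "diffpop_validation_error")
  }
  tibble(
    fraction_index = seq_along(methanol_pct),
    methanol_pct = as.numeric(methanol_pct)
  )
}

# Coerce a design argument (tibble from fractionation_design(), or a bare
# numeric ladder) to the canonical tibble, re-validating along the way.
as_fractionation_design <- function(design) {
  if (is.data.frame(design)) {
    if (!all(c("fraction_index", "methanol_pct") %in% names(design))) {
      stop_diffpop(
        "a design data frame needs `fraction_index` and `methanol_pct`",
        class = "diffpop_validation_error"
      )
    }
    design <- design[order(design$fraction_index), ]
    return(fractionation_design(design$methanol_pct))
  }
  fractionation_design(design)
}
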
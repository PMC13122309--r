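# ggplot2 figures for the main result types.

#' Plot precipitation profiles for selected proteins
#'
#' Draws per-fraction intensity (normalized to shares within each
#' replicate) against fraction index for both conditions, one facet per
#' protein -- the standard visual for judging a stabilization shift.
#'
#' @param data Long-format DiffPOP tibble (see [score_shifts()] for the
#'   schema).
#' @param proteins Protein IDs to plot (default: first 4 in the data).
#' @param normalize If `TRUE` (default), plot within-replicate shares
#'   rather than raw intensities.
#'
#' @return A ggplot object.
#' @export
plot_profiles <- function(data, proteins = NULL, normalize = TRUE) {
  if (is.null(proteins)) {
    proteins <- head(unique(data$protein_id), 4)
  }
  d <- dplyr::filter(data, .data$protein_id %in% proteins)
  d$intensity[is.na(d$intensity)] <- 0
  if (normalize) {
    d <- dplyr::mutate(
      dplyr::group_by(d, .data$protein_id, .data$condition,
                      .data$replicate),
      intensity = .data$intensity / sum(.data$intensity)
    )
    d <- dplyr::ungroup(d)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction_index,
                                  y = .data$intensity,
                                  colour = .data$condition,
                                  group = interaction(.data$condition,
                                                      .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein_id)) +
    ggplot2::labs(x = "Fraction", y = if (normalize) "Share" else
      "Intensity", colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-abundance results
#'
#' @param results Output of [differential_test()] or [dia_differential()],
#'   optionally already passed through [volcano_call()].
#' @param p_cut,fc_cut Cutoffs drawn as reference lines (and used to call
#'   proteins if `results` has no `call` column).
#'
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, p_cut = 0.05, fc_cut = 0.38) {
  if (!"call" %in% names(results)) {
    results <- volcano_call(results, p_cut = p_cut, fc_cut = fc_cut)
  }
  # cap -log10 p for the degenerate zero-p corner case so the plot renders
  logp <- -log10(pmax(results$p_raw, 1e-300))
  results$neg_log10_p <- logp
  ggplot2::ggplot(results, ggplot2::aes(x = .data$log2fc,
                                        y = .data$neg_log10_p,
                                        colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (compound / vehicle)",
                  y = "-log10 raw p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a concentration-time profile with LLOQ and threshold lines
#'
#' @param data Tibble with `time_h`, `conc`, and optionally `below_lloq`.
#' @param lloq,threshold Optional horizontal reference concentrations.
#'
#' @return A ggplot object (log10 concentration axis).
#' @export
plot_pk <- function(data, lloq = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h,
                                          y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Concentration") +
    ggplot2::theme_minimal()
  if (!is.null(lloq)) {
    p <- p + ggplot2::geom_hline(yintercept = lloq, linetype = "dotted")
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed")
  }
  p
}

#' @rdname fit_four_pl
#' @param object An `ic50_fit` object.
#' @method autoplot ic50_fit
#' @export
autoplot.ic50_fit <- function(object, ...) {
  grid <- tibble(dose = 10^seq(log10(min(object$data$dose)),
                               log10(max(object$data$dose)),
                               length.out = 200))
  grid$response <- object$bottom + (object$top - object$bottom) /
    (1 + (grid$dose / object$ic50)^object$hill)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                            y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2980b9") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose", y = "Response (%)") +
    ggplot2::theme_minimal()
}
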
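#' Default TMT 6-plex channel map
#'
#' Three biological replicates per condition, with vehicle and compound
#' alternating across the six reporter channels (the labeling layout used
#' in the OVCAR3 study: 126.1 vehicle N1, 127.1 compound N1, ...).
#'
#' @return A tibble with columns `channel`, `condition`, `replicate`.
#' @examples
#' tmt_channel_map()
#' @export
tmt_channel_map <- function() {
  tibble(
    channel = c("126.1", "127.1", "128.1", "129.1", "130.1", "131.1"),
    condition = rep(c("vehicle", "compound"), 3),
    replicate = rep(1:3, each = 2)
  )
}

validate_channel_map <- function(channel_map) {
  req <- c("channel", "condition", "replicate")
  if (!is.data.frame(channel_map) || !all(req %in% names(channel_map))) {
    stop_diffpop("channel map needs columns channel, condition, replicate",
                 class = "diffpop_validation_error")
  }
  if (anyDuplicated(channel_map$channel)) {
    stop_diffpop("channel map must assign each channel once",
                 class = "diffpop_validation_error")
  }
  counts <- table(channel_map$condition)
  if (length(counts) != 2L) {
    stop_diffpop("channel map must contain exactly two conditions",
                 class = "diffpop_validation_error")
  }
  invisible(channel_map)
}

#' Simulate a TMT 6-plex reporter-intensity matrix
#'
#' Draws log-normal protein intensities for six reporter channels (three
#' vehicle, three compound biological replicates), plants a mean log2
#' offset of `log2fc_planted` in the compound channels of `n_regulated`
#' randomly chosen proteins, and masks entries missing completely at
#' random at rate `missing_rate`.
#'
#' @param n_proteins Number of proteins.
#' @param n_regulated Number of proteins with a planted fold change.
#' @param log2fc_planted Mean log2 offset of regulated proteins in the
#'   compound channels (sign gives direction).
#' @param sigma Per-channel standard deviation on the log2 scale
#'   (>= 0; 0 gives noise-free data).
#' @param missing_rate Probability in [0, 1) that any single entry is
#'   recorded missing.
#' @param base_meanlog2,base_sdlog2 Mean and SD of per-protein baseline
#'   abundance on the log2 scale.
#' @param seed Integer seed.
#'
#' @return A list with `matrix` (tibble: `protein_id` + six channel
#'   columns), `channel_map` (see [tmt_channel_map()]), and `truth`
#'   (tibble: `protein_id`, `is_regulated`, `log2fc_planted`).
#' @examples
#' sim <- simulate_tmt(n_proteins = 50, n_regulated = 5, seed = 1)
#' head(sim$matrix)
#' @export
simulate_tmt <- function(n_proteins = 1000, n_regulated = 50,
                         log2fc_planted = 1, sigma = 0.25,
                         missing_rate = 0.02,
                         base_meanlog2 = 20, base_sdlog2 = 2,
                         seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  n_regulated <- check_count(n_regulated, "n_regulated", min = 0L)
  if (n_regulated > n_proteins) {
    stop_diffpop("`n_regulated` must not exceed `n_proteins`",
                 class = "diffpop_validation_error")
  }
  check_number(sigma, "sigma", min = 0)
  check_number(missing_rate, "missing_rate", min = 0, max = 1,
               allow_max = FALSE)
  map <- tmt_channel_map()

  withr::with_seed(seed, {
    ids <- protein_ids(n_proteins)
    regulated <- if (n_regulated > 0) sample(ids, n_regulated) else character()
    base <- rnorm(n_proteins, base_meanlog2, base_sdlog2)
    m <- matrix(base, nrow = n_proteins, ncol = 6)
    effect <- ifelse(ids %in% regulated, log2fc_planted, 0)
    compound_cols <- which(map$condition == "compound")
    m[, compound_cols] <- m[, compound_cols] + effect
    m <- m + matrix(rnorm(n_proteins * 6, 0, sigma), nrow = n_proteins)
    intensities <- 2^m
    if (missing_rate > 0) {
      mask <- matrix(runif(n_proteins * 6) < missing_rate,
                     nrow = n_proteins)
      intensities[mask] <- NA_real_
    }
    colnames(intensities) <- map$channel
    out <- as_tibble(intensities)
    out <- dplyr::bind_cols(tibble(protein_id = ids), out)
    truth <- tibble(
      protein_id = ids,
      is_regulated = ids %in% regulated,
      log2fc_planted = effect
    )
    list(matrix = out, channel_map = map, truth = truth)
  })
}

#' Simulate a multi-cell-line DIA proteomics panel
#'
#' For each cell line, generates a protein-by-injection intensity matrix
#' with six injections per condition (three biological replicates, two
#' technical injections each). Each line has its own regulated protein
#' set; a shared regulated core, present in every line's set, emulates a
#' compound's consistent downstream signature across cell lines, so the
#' downstream multi-line intersection recovers it.
#'
#' @param cell_lines Character vector of cell-line names.
#' @param n_proteins Number of proteins (shared identifier space).
#' @param shared_core_ids Protein IDs regulated in every line; defaults to
#'   the first 14 proteins (a core the size of the signature recovered in
#'   the motivating study). Must be a subset of every line's regulated set.
#' @param per_line_regulated Named list (one element per cell line) of
#'   regulated protein IDs; defaults to the shared core plus
#'   `n_extra_per_line` line-specific random proteins.
#' @param n_extra_per_line Line-specific regulated proteins beyond the
#'   core when `per_line_regulated` is `NULL`.
#' @param log2fc Planted mean log2 offset for regulated proteins.
#' @param sigma Per-injection SD on the log2 scale.
#' @param missing_rate Missing-completely-at-random rate per entry.
#' @param n_bio,n_tech Biological replicates and technical injections per
#'   condition.
#' @param base_meanlog2,base_sdlog2 Baseline log2-abundance distribution.
#' @param seed Integer seed.
#'
#' @return A list with `matrices` (named list of tibbles: `protein_id` +
#'   one column per injection, named `<condition>_b<bio>_t<tech>`),
#'   `condition_map` (tibble: `injection`, `condition`, `bio_rep`,
#'   `tech_rep`), and `truth` (tibble: `protein_id`, `cell_line`,
#'   `is_regulated`, `in_shared_core`).
#' @examples
#' sim <- simulate_dia_panel(n_proteins = 100, seed = 1)
#' names(sim$matrices)
#' @export
simulate_dia_panel <- function(cell_lines = c("OVCAR3", "OV231", "PEO1",
                                              "OV81.2"),
                               n_proteins = 500,
                               shared_core_ids = NULL,
                               per_line_regulated = NULL,
                               n_extra_per_line = 20,
                               log2fc = 1, sigma = 0.25,
                               missing_rate = 0.02,
                               n_bio = 3, n_tech = 2,
                               base_meanlog2 = 20, base_sdlog2 = 2,
                               seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  check_number(sigma, "sigma", min = 0)
  check_number(missing_rate, "missing_rate", min = 0, max = 1,
               allow_max = FALSE)
  ids <- protein_ids(n_proteins)
  if (anyDuplicated(ids)) {
    stop_diffpop("duplicate protein IDs", class = "diffpop_validation_error")
  }
  if (is.null(shared_core_ids)) {
    shared_core_ids <- head(ids, min(14L, n_proteins))
  }
  if (!all(shared_core_ids %in% ids)) {
    stop_diffpop("`shared_core_ids` must be drawn from the protein IDs",
                 class = "diffpop_validation_error")
  }
  if (anyDuplicated(shared_core_ids)) {
    stop_diffpop("duplicate protein IDs in `shared_core_ids`",
                 class = "diffpop_validation_error")
  }

  cmap <- tidyr::expand_grid(
    condition = c("vehicle", "compound"),
    bio_rep = seq_len(n_bio),
    tech_rep = seq_len(n_tech)
  )
  cmap$injection <- sprintf("%s_b%d_t%d", cmap$condition, cmap$bio_rep,
                            cmap$tech_rep)
  cmap <- cmap[, c("injection", "condition", "bio_rep", "tech_rep")]
  n_inj <- nrow(cmap)

  withr::with_seed(seed, {
    if (is.null(per_line_regulated)) {
      pool <- setdiff(ids, shared_core_ids)
      per_line_regulated <- lapply(cell_lines, function(cl) {
        extra <- sample(pool, min(n_extra_per_line, length(pool)))
        c(shared_core_ids, extra)
      })
      names(per_line_regulated) <- cell_lines
    }
    if (!setequal(names(per_line_regulated), cell_lines)) {
      stop_diffpop("`per_line_regulated` must name every cell line",
                   class = "diffpop_validation_error")
    }
    ok_core <- vapply(per_line_regulated,
                      function(s) all(shared_core_ids %in% s), logical(1))
    if (!all(ok_core)) {
      stop_diffpop(
        "`shared_core_ids` must be contained in every line's regulated set",
        class = "diffpop_validation_error"
      )
    }

    matrices <- list()
    truth <- list()
    for (cl in cell_lines) {
      reg <- per_line_regulated[[cl]]
      base <- rnorm(n_proteins, base_meanlog2, base_sdlog2)
      m <- matrix(base, nrow = n_proteins, ncol = n_inj)
      effect <- ifelse(ids %in% reg, log2fc, 0)
      compound_cols <- which(cmap$condition == "compound")
      m[, compound_cols] <- m[, compound_cols] + effect
      m <- m + matrix(rnorm(n_proteins * n_inj, 0, sigma),
                      nrow = n_proteins)
      intensities <- 2^m
      if (missing_rate > 0) {
        mask <- matrix(runif(n_proteins * n_inj) < missing_rate,
                       nrow = n_proteins)
        intensities[mask] <- NA_real_
      }
      colnames(intensities) <- cmap$injection
      matrices[[cl]] <- dplyr::bind_cols(tibble(protein_id = ids),
                                         as_tibble(intensities))
      truth[[cl]] <- tibble(
        protein_id = ids,
        cell_line = cl,
        is_regulated = ids %in% reg,
        in_shared_core = ids %in% shared_core_ids
      )
    }
    list(matrices = matrices, condition_map = cmap,
         truth = dplyr::bind_rows(truth))
  })
}
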
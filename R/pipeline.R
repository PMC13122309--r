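#' Run the DiffPOP shift pipeline end to end
#'
#' Validates the configuration, obtains the long-format dataset (either by
#' reading `input` or by simulating with the `simulate` parameters),
#' scores every protein, calls candidate targets, and writes the stage
#' outputs into `out_dir`: the dataset and truth table (when simulated),
#' the full score table, the candidate table, a JSON + text run report,
#' and a manifest recording the configuration, seed, input digests and
#' package version. Identical configuration and seed reproduce identical
#' outputs (the manifest timestamp aside).
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `out_dir` (required), and optionally `input` (path to a DiffPOP TSV),
#'   `simulate` (list of [simulate_diffpop()] arguments, used when no
#'   `input` is given), `design` (numeric ladder), `quantile` (default
#'   0.03), `spearman_gate` (default 0.7), `require_stabilized` (default
#'   `TRUE`), `seed` (default 1).
#' @param seed Optional seed overriding the configuration entry.
#'
#' @return Invisibly, a list with `results`, `candidates`, `paths`, and
#'   (when simulated) `truth`.
#' @examples
#' out <- run_diffpop_pipeline(list(
#'   out_dir = tempfile("run"),
#'   simulate = list(n_proteins = 30, n_targets = 2, noise_cv = 0),
#'   seed = 7
#' ))
#' out$candidates
#' @export
run_diffpop_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$out_dir)) {
    stop_diffpop("config must be a list (or YAML file) with an `out_dir`",
                 class = "diffpop_validation_error")
  }
  quantile <- config$quantile %||% 0.03
  spearman_gate <- config$spearman_gate %||% 0.7
  require_stabilized <- config$require_stabilized %||% TRUE
  config$seed <- seed %||% config$seed %||% 1L
  # validate before any work
  check_number(quantile, "quantile", min = 0, max = 1, allow_min = FALSE)
  check_number(spearman_gate, "spearman_gate", min = -1, max = 1)
  design <- if (!is.null(config$design)) {
    as_fractionation_design(config$design)
  } else {
    fractionation_design()
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  truth <- NULL
  input_digest <- NULL

  if (!is.null(config$input)) {
    data <- read_diffpop_table(config$input)
    input_digest <- unname(tools::md5sum(config$input))
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$design <- design
    sim_args$seed <- config$seed
    sim <- do.call(simulate_diffpop, sim_args)
    data <- sim$data
    truth <- sim$truth
    paths$data <- file.path(out_dir, "diffpop_data.tsv")
    write_diffpop_table(data, paths$data)
    paths$truth <- file.path(out_dir, "diffpop_truth.tsv")
    readr::write_tsv(truth, paths$truth)
  }

  results <- score_shifts(data, design = design,
                          spearman_gate = spearman_gate)
  annotated <- call_targets(results, quantile = quantile,
                            require_stabilized = require_stabilized,
                            .keep_all = TRUE)
  candidates <- dplyr::filter(annotated, .data$is_candidate)

  paths$results <- file.path(out_dir, "shift_results.tsv")
  readr::write_tsv(annotated, paths$results)
  paths$candidates <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(candidates, paths$candidates)

  report <- list(
    n_proteins = length(unique(data$protein_id)),
    n_scored = sum(results$scored),
    n_excluded = sum(!results$scored),
    excluded_reasons = as.list(table(results$reason[!results$scored])),
    quantile = quantile,
    spearman_gate = spearman_gate,
    n_rank_cut = ceiling(quantile * sum(results$scored)),
    n_candidates = nrow(candidates),
    candidates = candidates$protein_id
  )
  paths$report <- file.path(out_dir, "report")
  write_report(report, paths$report)

  manifest <- list(
    package = "diffpop",
    version = as.character(utils::packageVersion("diffpop")),
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    input_md5 = input_digest,
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(results = annotated, candidates = candidates,
                 truth = truth, paths = paths))
}

#' Write a stage report as machine-readable JSON plus a text summary
#'
#' The JSON twin contains every number that appears in the text summary;
#' reloading the JSON recovers the in-memory values.
#'
#' @param report Named list of scalars, vectors, and nested lists.
#' @param path_prefix Output path without extension; `<prefix>.json` and
#'   `<prefix>.txt` are written.
#'
#' @return Invisibly, the two paths.
#' @examples
#' write_report(list(n_candidates = 0), tempfile())
#' @export
write_report <- function(report, path_prefix) {
  if (!is.list(report) || is.null(names(report)) ||
      any(names(report) == "")) {
    stop_diffpop("`report` must be a fully named list",
                 class = "diffpop_validation_error")
  }
  json_path <- paste0(path_prefix, ".json")
  txt_path <- paste0(path_prefix, ".txt")
  payload <- c(list(report_schema = "diffpop-report/1"), report)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  render <- function(x, name, indent = "") {
    if (is.list(x)) {
      c(sprintf("%s%s:", indent, name),
        unlist(purrr::imap(x, render, indent = paste0(indent, "  "))))
    } else if (length(x) == 0) {
      sprintf("%s%s: (none)", indent, name)
    } else {
      sprintf("%s%s: %s", indent, name,
              paste(format(x, digits = 15), collapse = ", "))
    }
  }
  lines <- unlist(purrr::imap(report, render))
  ok <- tryCatch({
    writeLines(c("diffpop stage report", lines), txt_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_diffpop(sprintf("cannot write report to %s", txt_path),
                 class = "diffpop_io_error")
  }
  invisible(c(json = json_path, txt = txt_path))
}
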
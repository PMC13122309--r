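# Readers and writers for the pipeline's tab-separated interchange
# schemas. Every writer/reader pair round-trips values exactly (full
# precision TSV); unknown columns are preserved on read but ignored by
# the analysis.

diffpop_schemas <- list(
  diffpop_long = list(
    required = c("protein_id", "condition", "replicate", "fraction_index",
                 "methanol_pct", "intensity"),
    key = c("protein_id", "condition", "replicate", "fraction_index")
  ),
  pk_profile = list(
    required = c("time_h", "conc"),
    key = "time_h"
  ),
  dose_response = list(
    required = c("dose", "response"),
    key = NULL
  )
)

validate_schema <- function(data, schema_name) {
  schema <- diffpop_schemas[[schema_name]]
  if (is.null(schema)) {
    stop_diffpop(sprintf("unknown schema `%s`", schema_name),
                 class = "diffpop_validation_error")
  }
  missing_cols <- setdiff(schema$required, names(data))
  if (length(missing_cols) > 0) {
    stop_diffpop(
      sprintf("schema `%s`: missing required column(s): %s", schema_name,
              paste(missing_cols, collapse = ", ")),
      class = "diffpop_schema_error"
    )
  }
  for (col in schema$required) {
    if (col %in% c("protein_id", "condition")) next
    if (!is.numeric(data[[col]]) && !is.logical(data[[col]])) {
      stop_diffpop(
        sprintf("schema `%s`: column `%s` must be numeric", schema_name,
                col),
        class = "diffpop_schema_error"
      )
    }
  }
  if (!is.null(schema$key)) {
    keys <- do.call(paste, c(data[schema$key], sep = "\r"))
    dup <- which(duplicated(keys))
    if (length(dup) > 0) {
      stop_diffpop(
        sprintf("schema `%s`: duplicate key (%s) in row %d: %s",
                schema_name, paste(schema$key, collapse = ", "), dup[1],
                gsub("\r", " / ", keys[dup[1]])),
        class = "diffpop_schema_error"
      )
    }
  }
  invisible(data)
}

#' Read and write the pipeline's TSV tables
#'
#' `read_diffpop_table()` reads the long-format precipitation-profile
#' table and validates its schema (required columns, numeric types,
#' unique protein/condition/replicate/fraction keys); the matching
#' writers emit full-precision TSV so a write-read round trip is
#' value-identical. `read_pk_profile()` / `read_dose_response()` handle
#' the concentration-time and dose-viability tables the same way.
#'
#' @param path File path.
#' @param verbose If `TRUE`, log row counts and missingness on read.
#'
#' @return A validated tibble.
#' @export
read_diffpop_table <- function(path, verbose = FALSE) {
  data <- read_tsv_checked(path)
  data <- validate_schema(data, "diffpop_long")
  if (!"is_missing" %in% names(data)) {
    data$is_missing <- is.na(data$intensity)
  }
  if (verbose) {
    inform(sprintf("read %d rows (%d proteins, %.1f%% missing) from %s",
                   nrow(data), length(unique(data$protein_id)),
                   100 * mean(data$is_missing), path))
  }
  data
}

#' @rdname read_diffpop_table
#' @param data Table to write.
#' @export
write_diffpop_table <- function(data, path) {
  validate_schema(data, "diffpop_long")
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname read_diffpop_table
#' @export
read_pk_profile <- function(path, verbose = FALSE) {
  data <- read_tsv_checked(path)
  data <- validate_schema(data, "pk_profile")
  if (!"below_lloq" %in% names(data)) data$below_lloq <- FALSE
  if (verbose) {
    inform(sprintf("read %d timepoints (%d below LLOQ) from %s",
                   nrow(data), sum(data$below_lloq), path))
  }
  data
}

#' @rdname read_diffpop_table
#' @export
write_pk_profile <- function(data, path) {
  validate_schema(data, "pk_profile")
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname read_diffpop_table
#' @export
read_dose_response <- function(path, verbose = FALSE) {
  data <- read_tsv_checked(path)
  data <- validate_schema(data, "dose_response")
  if (verbose) {
    inform(sprintf("read %d dose-response rows from %s", nrow(data), path))
  }
  data
}

#' Read and write a TMT reporter matrix with its channel-map sidecar
#'
#' The matrix is a TSV with `protein_id` plus one column per reporter
#' channel; the channel map travels in a small YAML sidecar mapping each
#' channel to its condition and biological replicate.
#'
#' @param path Matrix TSV path; the sidecar defaults to
#'   `<path>.channels.yaml`.
#' @param map_path Channel-map sidecar path.
#'
#' @return `read_reporter_matrix()` returns a list with `matrix` and
#'   `channel_map`.
#' @export
read_reporter_matrix <- function(path,
                                 map_path = paste0(path, ".channels.yaml")) {
  channel_map <- read_channel_map(map_path)
  matrix <- read_tsv_checked(path)
  check_reporter_matrix(matrix, channel_map$channel)
  list(matrix = matrix, channel_map = channel_map)
}

#' @rdname read_reporter_matrix
#' @param matrix Reporter matrix tibble.
#' @param channel_map Channel map tibble (see [tmt_channel_map()]).
#' @export
write_reporter_matrix <- function(matrix, path,
                                  channel_map = tmt_channel_map(),
                                  map_path = paste0(path,
                                                    ".channels.yaml")) {
  check_reporter_matrix(matrix, channel_map$channel)
  readr::write_tsv(matrix, path)
  sidecar <- lapply(seq_len(nrow(channel_map)), function(i) {
    list(condition = channel_map$condition[i],
         replicate = channel_map$replicate[i])
  })
  names(sidecar) <- channel_map$channel
  yaml::write_yaml(sidecar, map_path)
  invisible(path)
}

read_channel_map <- function(map_path) {
  if (!file.exists(map_path)) {
    stop_diffpop(sprintf("channel map sidecar not found: %s", map_path),
                 class = "diffpop_schema_error")
  }
  raw <- yaml::read_yaml(map_path)
  tibble(
    channel = names(raw),
    condition = vapply(raw, function(x) x$condition, character(1)),
    replicate = vapply(raw, function(x) as.integer(x$replicate),
                       integer(1))
  )
}

#' @rdname read_reporter_matrix
#' @export
read_dia_matrix <- function(path) {
  matrix <- read_tsv_checked(path)
  check_dia_matrix(matrix)
  matrix
}

#' @rdname read_reporter_matrix
#' @export
write_dia_matrix <- function(matrix, path) {
  check_dia_matrix(matrix)
  readr::write_tsv(matrix, path)
  invisible(path)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) {
    stop_diffpop(sprintf("file not found: %s", path),
                 class = "diffpop_io_error")
  }
  data <- readr::read_tsv(path, show_col_types = FALSE,
                          progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop_diffpop(
      sprintf("parse error in %s at row %d: expected %s", path,
              probs$row[1], probs$expected[1]),
      class = "diffpop_schema_error"
    )
  }
  data
}
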
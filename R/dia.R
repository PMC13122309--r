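#' Derive the injection-to-condition map from DIA column names
#'
#' DIA matrices written by [simulate_dia_panel()] (and real exports using
#' the same layout) name injections `<condition>_b<bio>_t<tech>`; the
#' condition is everything before the first underscore.
#'
#' @param matrix DIA matrix (tibble: `protein_id` + injection columns).
#'
#' @return Tibble with `injection` and `condition`.
#' @export
dia_condition_map <- function(matrix) {
  injections <- setdiff(names(matrix), "protein_id")
  tibble(
    injection = injections,
    condition = sub("_.*$", "", injections)
  )
}

#' Presence filter for DIA matrices
#'
#' Keeps proteins quantified in at least `min_per_condition` of the
#' injections of *each* condition, the minimum needed for a p-value to
#' exist. Kept and dropped counts are recorded in the `"presence_filter"`
#' attribute.
#'
#' @param matrix DIA matrix (tibble: `protein_id` + injection columns).
#' @param condition_map Tibble with `injection` and `condition`; derived
#'   from the column names when `NULL`.
#' @param min_per_condition Minimum non-missing injections per condition.
#'
#' @return The filtered matrix.
#' @examples
#' sim <- simulate_dia_panel(n_proteins = 50, missing_rate = 0.3, seed = 1)
#' dia_presence_filter(sim$matrices[[1]])
#' @export
dia_presence_filter <- function(matrix, condition_map = NULL,
                                min_per_condition = 2) {
  min_per_condition <- check_count(min_per_condition, "min_per_condition",
                                   min = 1L)
  cm <- check_dia_matrix(matrix, condition_map)
  keep <- rep(TRUE, nrow(matrix))
  for (cond in unique(cm$condition)) {
    cols <- cm$injection[cm$condition == cond]
    n_obs <- rowSums(!is.na(as.matrix(matrix[, cols])))
    keep <- keep & n_obs >= min_per_condition
  }
  out <- matrix[keep, , drop = FALSE]
  attr(out, "presence_filter") <- list(
    kept = sum(keep), dropped = sum(!keep),
    min_per_condition = min_per_condition
  )
  out
}

#' Per-protein differential abundance on pooled DIA injections
#'
#' All injections of a condition -- biological replicates and technical
#' injections alike -- are pooled as observations, mirroring how the
#' merged per-condition fold changes and p-values are computed in practice
#' for this design (the pseudo-replication this introduces is deliberate
#' and documented). The test is the unequal-variance (Welch) two-sample
#' t on log2 intensities, using the available non-missing values, so
#' unbalanced missingness is handled.
#'
#' @param matrix DIA matrix, ideally after [dia_presence_filter()].
#' @param condition_map Tibble with `injection` and `condition`; derived
#'   from the column names when `NULL`.
#' @param transform `"log2"` for raw intensities (default), `"identity"`
#'   for already-log values.
#'
#' @return Tibble with `protein_id`, `log2fc`, `t_stat`, `df`, `p_raw`,
#'   `degenerate`.
#' @examples
#' sim <- simulate_dia_panel(n_proteins = 50, seed = 1)
#' dia_differential(dia_presence_filter(sim$matrices[[1]]))
#' @export
dia_differential <- function(matrix, condition_map = NULL,
                             transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  cm <- check_dia_matrix(matrix, condition_map)
  conds <- unique(cm$condition)
  if (!setequal(conds, c("vehicle", "compound"))) {
    stop_diffpop("conditions must be `vehicle` and `compound`",
                 class = "diffpop_validation_error")
  }
  m <- as.matrix(matrix[, cm$injection])
  if (transform == "log2") {
    if (any(m <= 0, na.rm = TRUE)) {
      stop_diffpop("raw intensities must be positive for log2 transform",
                   class = "diffpop_validation_error")
    }
    m <- log2(m)
  }
  veh <- m[, cm$injection[cm$condition == "vehicle"], drop = FALSE]
  cmp <- m[, cm$injection[cm$condition == "compound"], drop = FALSE]
  res <- row_t_test(veh, cmp, var_equal = FALSE)
  tibble(
    protein_id = matrix$protein_id,
    log2fc = res$estimate,
    t_stat = res$t_stat,
    df = res$df,
    p_raw = res$p_raw,
    degenerate = res$degenerate
  )
}

#' Intersect significant protein sets across cell lines
#'
#' Returns the proteins significant in every set, together with per-set
#' sizes, pairwise overlap counts, and the cardinality of every exclusive
#' Venn region (all non-empty combinations of membership), supporting the
#' usual up-to-four-set Venn diagram.
#'
#' @param sets Named list of character vectors (one significant-protein
#'   set per cell line); unnamed sets are labelled `set1`, `set2`, ...
#'
#' @return A list with `intersection` (sorted character vector),
#'   `set_sizes` (named integer), `pairwise` (matrix of overlap counts),
#'   and `regions` (tibble: `region`, `size`, exclusive Venn regions).
#' @examples
#' intersect_significant(list(a = c("A", "B", "C"), b = c("B", "C"),
#'                            c = c("B", "C", "D"), d = c("B", "C")))
#' @export
intersect_significant <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L) {
    stop_diffpop("`sets` must be a non-empty list of character vectors",
                 class = "diffpop_validation_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 0L) {
    membership <- base::matrix(logical(0), nrow = 0, ncol = length(sets),
                               dimnames = list(NULL, names(sets)))
  }
  if (is.null(dim(membership))) {
    membership <- base::matrix(membership, nrow = length(universe),
                               dimnames = list(NULL, names(sets)))
  }
  inter <- if (length(universe) > 0) {
    universe[rowSums(membership) == length(sets)]
  } else {
    character()
  }
  n <- length(sets)
  pairwise <- crossprod(membership * 1L)
  combos <- unlist(lapply(seq_len(n), function(k) {
    combn(names(sets), k, simplify = FALSE)
  }), recursive = FALSE)
  regions <- purrr::map_dfr(combos, function(combo) {
    inside <- rowSums(membership[, combo, drop = FALSE]) == length(combo)
    outside_cols <- setdiff(names(sets), combo)
    outside <- if (length(outside_cols) == 0) {
      rep(TRUE, length(universe))
    } else {
      rowSums(membership[, outside_cols, drop = FALSE]) == 0
    }
    tibble(region = paste(combo, collapse = "&"),
           size = sum(inside & outside))
  })
  list(
    intersection = sort(inter),
    set_sizes = vapply(sets, length, integer(1)),
    pairwise = pairwise,
    regions = regions
  )
}

check_dia_matrix <- function(matrix, condition_map = NULL) {
  if (!is.data.frame(matrix) || !"protein_id" %in% names(matrix)) {
    stop_diffpop("DIA matrix needs a `protein_id` column",
                 class = "diffpop_schema_error")
  }
  if (anyDuplicated(matrix$protein_id)) {
    stop_diffpop("duplicate protein IDs in DIA matrix",
                 class = "diffpop_schema_error")
  }
  if (is.null(condition_map)) condition_map <- dia_condition_map(matrix)
  missing_inj <- setdiff(condition_map$injection, names(matrix))
  if (length(missing_inj) > 0) {
    stop_diffpop(paste0("matrix is missing injection column(s): ",
                        paste(missing_inj, collapse = ", ")),
                 class = "diffpop_schema_error")
  }
  condition_map
}
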
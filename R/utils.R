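# Internal helpers shared across modules.

stop_diffpop <- function(message, class = "diffpop_error", ...) {
  abort(message, class = c(class, "diffpop_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_min = TRUE, allow_max = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_min) x >= min else x > min) &&
    (if (allow_max) x <= max else x < max)
  if (!ok) {
    stop_diffpop(
      sprintf("`%s` must be a single finite number in %s%s, %s%s; got %s",
              name,
              if (allow_min) "[" else "(", format(min),
              format(max), if (allow_max) "]" else ")",
              paste(format(x), collapse = ", ")),
      class = "diffpop_validation_error"
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == trunc(x) && x >= min
  if (!ok) {
    stop_diffpop(sprintf("`%s` must be a single integer >= %d", name, min),
                 class = "diffpop_validation_error")
  }
  invisible(as.integer(x))
}

# Row-wise two-sample location test on matrices (proteins in rows).
# Returns estimate = rowMeans(b) - rowMeans(a), two-sided p, df, and a
# degenerate flag for the zero-spread corner cases: zero pooled spread with
# equal means -> p = 1 (no evidence); with unequal means -> p = 0, flagged.
row_t_test <- function(a, b, var_equal = TRUE) {
  n_a <- rowSums(!is.na(a))
  n_b <- rowSums(!is.na(b))
  if (any(n_a < 2L) || any(n_b < 2L)) {
    stop_diffpop("each group needs at least 2 observations per protein",
                 class = "diffpop_validation_error")
  }
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  var_a <- rowSums((a - mean_a)^2, na.rm = TRUE) / (n_a - 1L)
  var_b <- rowSums((b - mean_b)^2, na.rm = TRUE) / (n_b - 1L)
  est <- mean_b - mean_a
  if (var_equal) {
    df <- n_a + n_b - 2L
    sp2 <- ((n_a - 1L) * var_a + (n_b - 1L) * var_b) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    se2_a <- var_a / n_a
    se2_b <- var_b / n_b
    se <- sqrt(se2_a + se2_b)
    df <- (se2_a + se2_b)^2 /
      (se2_a^2 / (n_a - 1L) + se2_b^2 / (n_b - 1L))
  }
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, NA_real_, est / se)
  p <- ifelse(degenerate,
              ifelse(est == 0, 1, 0),
              2 * pt(-abs(t_stat), df))
  df[degenerate & est == 0] <- NA_real_
  tibble(
    estimate = est, t_stat = t_stat, df = as.numeric(df),
    p_raw = p, degenerate = degenerate & est != 0
  )
}

#' @importFrom stats pt
NULL

# Mean-one multiplicative lognormal noise factors for a given CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

protein_ids <- function(n, prefix = "P") {
  sprintf("%s%04d", prefix, seq_len(n))
}
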
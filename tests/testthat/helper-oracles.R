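# Independent oracles and small fixture builders used across tests.

# Brute-force maximum over prefix sums, independent of the cumsum-based
# implementation in the package.
brute_force_ks <- function(a, b) {
  best <- 0
  for (j in seq_along(a)) {
    best <- max(best, abs(sum(a[seq_len(j)]) - sum(b[seq_len(j)])))
  }
  best
}

# Random normalized 9-fraction profile (Dirichlet-like via normalized
# exponentials).
random_profile <- function(n = 9) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Minimal long-format DiffPOP table for hand-built profiles: one protein,
# both conditions, replicates as columns of the supplied matrices.
profile_table <- function(protein_id, vehicle, compound,
                          design = fractionation_design()) {
  build <- function(mat, cond) {
    mat <- as.matrix(mat)
    do.call(rbind, lapply(seq_len(ncol(mat)), function(r) {
      data.frame(
        protein_id = protein_id, condition = cond, replicate = r,
        fraction_index = design$fraction_index,
        methanol_pct = design$methanol_pct,
        intensity = mat[, r]
      )
    }))
  }
  tibble::as_tibble(rbind(build(vehicle, "vehicle"),
                          build(compound, "compound")))
}
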
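make_dia <- function(values, n_proteins = nrow(values)) {
  cmap <- tidyr::expand_grid(condition = c("vehicle", "compound"),
                             bio = 1:3, tech = 1:2)
  cols <- sprintf("%s_b%d_t%d", cmap$condition, cmap$bio, cmap$tech)
  m <- matrix(values, ncol = 12, byrow = TRUE)
  colnames(m) <- cols
  dplyr::bind_cols(
    tibble::tibble(protein_id = sprintf("P%d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
}

test_that("presence filter keeps proteins observable in both conditions", {
  v <- rep(100, 12)
  p1 <- v; p1[1:5] <- NA                    # 1/6 vehicle, 6/6 compound
  p2 <- v; p2[c(1, 2, 3, 4, 7, 8, 9, 10)] <- NA  # 2/6 and 2/6
  p3 <- v                                   # fully observed
  m <- make_dia(c(p1, p2, p3))
  out <- dia_presence_filter(m)
  expect_equal(out$protein_id, c("P2", "P3"))
  info <- attr(out, "presence_filter")
  expect_equal(info$kept, 2)
  expect_equal(info$dropped, 1)
  # fully observed matrix passes unchanged
  full <- make_dia(rep(100, 24))
  expect_equal(dia_presence_filter(full), full, ignore_attr = TRUE)
})

test_that("pooled DIA test uses available injections and matches Welch", {
  # noise-free planted 2x change
  m <- make_dia(c(rep(10, 6), rep(20, 6)))
  res <- dia_differential(m)
  expect_equal(res$log2fc, 1)

  # one missing technical injection: computed on the remaining 5 vs 6
  vals <- c(10, 11, 12, 10, 11, NA, 21, 20, 22, 19, 20, 21)
  m2 <- make_dia(vals)
  res2 <- dia_differential(m2)
  ref <- t.test(log2(vals[7:12]), log2(vals[1:5]), var.equal = FALSE)
  expect_equal(res2$p_raw, ref$p.value)
  expect_equal(res2$log2fc,
               mean(log2(vals[7:12])) - mean(log2(vals[1:5])))

  expect_error(
    dia_differential(make_dia(c(10, rep(NA, 5), rep(10, 6)))),
    class = "diffpop_validation_error"
  )
})

test_that("null DIA p-values are uniform", {
  sim <- simulate_dia_panel(cell_lines = "A", n_proteins = 2000,
                            shared_core_ids = character(),
                            per_line_regulated = list(A = character()),
                            sigma = 0.3, missing_rate = 0, seed = 13)
  res <- dia_differential(sim$matrices$A)
  ks <- suppressWarnings(stats::ks.test(res$p_raw, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(res$p_raw < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("set intersection matches brute force with full Venn regions", {
  sets <- list(a = c("A", "B", "C"), b = c("B", "C"),
               c = c("B", "C", "D"), d = c("B", "C"))
  out <- intersect_significant(sets)
  expect_equal(out$intersection, c("B", "C"))
  expect_equal(unname(out$set_sizes), c(3, 2, 3, 2))
  expect_equal(out$regions$size[out$regions$region == "a&b&c&d"], 2)
  expect_equal(out$regions$size[out$regions$region == "a"], 1)  # A only
  expect_equal(sum(out$regions$size), 4)  # regions partition the universe

  expect_equal(intersect_significant(list(x = c("q", "r")))$intersection,
               c("q", "r"))
  expect_equal(
    intersect_significant(list(a = "A", b = character()))$intersection,
    character(0)
  )

  withr::with_seed(19, {
    for (i in 1:20) {
      fam <- lapply(1:4, function(j) {
        sample(LETTERS, sample(0:12, 1))
      })
      names(fam) <- paste0("s", 1:4)
      got <- intersect_significant(fam)$intersection
      want <- sort(Reduce(intersect, fam))
      expect_equal(got, want)
      expect_equal(sum(intersect_significant(fam)$regions$size),
                   length(unique(unlist(fam))))
    }
  })
})

test_that("noise-free panel recovers a planted 14-protein shared core exactly", {
  ids <- sprintf("P%04d", 1:300)
  core <- ids[1:14]
  lines <- c("OVCAR3", "OV231", "PEO1", "OV81.2")
  # disjoint line-specific extras so the 4-way intersection is the core
  extras <- split(ids[15:54], rep(lines, each = 10))
  per_line <- lapply(lines, function(cl) c(core, extras[[cl]]))
  names(per_line) <- lines
  sim <- simulate_dia_panel(cell_lines = lines, n_proteins = 300,
                            shared_core_ids = core,
                            per_line_regulated = per_line,
                            log2fc = 1, sigma = 0, missing_rate = 0,
                            seed = 17)
  sets <- lapply(sim$matrices, function(m) {
    res <- volcano_call(dia_differential(dia_presence_filter(m)))
    res$protein_id[res$call != "ns"]
  })
  out <- intersect_significant(sets)
  expect_equal(out$intersection, sort(core))
  expect_length(out$intersection, 14)
  # single line: the intersection is that line's significant set
  expect_equal(intersect_significant(sets[1])$intersection,
               sort(sets[[1]]))
})
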
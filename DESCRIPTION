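Package: diffpop
Title: Differential Precipitation Proteomics for Drug Target Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for identifying small-molecule protein
    targets from differential precipitation (DiffPOP) proteomics:
    solvent-gradient precipitation profiles are normalized per protein,
    ligand-induced stabilization shifts are scored with a
    Kolmogorov-Smirnov statistic across fractions, and candidates are
    called with a quantile significance rule gated on replicate
    reproducibility. Companion stages cover TMT 6-plex and
    data-independent-acquisition differential abundance with multi-cell-line
    intersection, four-parameter logistic dose-response (IC50) fitting with
    a cytotoxic selectivity index, and noncompartmental pharmacokinetics
    (AUC, terminal slope, half-life, clearance, steady-state volume,
    bioavailability, time above a therapeutic threshold). A synthetic-data
    module generates every input the pipeline consumes, with planted
    ground truth, so the full analysis can be exercised and calibrated
    without any external download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
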
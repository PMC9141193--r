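Package: conexus
Title: Consensus Weighted Gene Co-Expression Networks for Multi-Cohort
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds consensus weighted gene co-expression networks across
    multiple transcriptomic cohorts and carries the analysis through to
    candidate marker panels. Per-cohort signed or unsigned adjacencies are
    soft-thresholded, converted to topological overlap matrices (TOM),
    quantile-calibrated across cohorts and combined by element-wise minimum
    into a consensus TOM. Consensus modules are detected by average-linkage
    clustering with eigengene-based merging and kME rescue, correlated with
    binary disease status and continuous lung-function traits (FVC, DLCO),
    screened by permutation Zsummary module preservation in independent test
    cohorts, and summarised by intramodular hub genes ranked with a HubScore
    combining module membership (kME) and trait gene significance (GS).
    Curated gene-set triage (secretome, known-disease, GWA lists; GMT input)
    and elastic-net logistic marker panels evaluated by precision-recall AUC
    with label-permutation significance complete the pipeline. A synthetic
    multi-cohort generator with planted modules and trait coupling makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
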
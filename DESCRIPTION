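Package: qsardyn
Title: GA-MLR QSAR Modelling with OECD Validation and Trajectory
    Cross-Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity
    relationship (QSAR) models by genetic-algorithm descriptor selection
    coupled to multiple linear regression, with the full OECD validation
    battery: leave-one-out and leave-many-out cross-validation,
    Y-scrambling permutation nulls, external-set metrics (Q2F1, Lin's
    concordance correlation, Roy's rm2), and a leverage-based
    applicability domain with Williams-plot diagnostics. Includes a
    two-stage descriptor pre-filter (near-constant and pairwise-collinear
    removal), fixture encodings of two published pIC50 equations for
    tubulin polymerization inhibitors, synthetic descriptor-table and
    trajectory generators with known ground truth, and post-simulation
    trajectory statistics: Kabsch superposition, RMSD series, per-site
    RMSF, and the dynamic cross-correlation matrix (DCCM).
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
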
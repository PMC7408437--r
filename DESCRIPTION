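Package: uhrnb
Title: Immune-Gene Biclustering Stratification of High-Risk Neuroblastoma
Version: 0.1.0
Authors@R: person("uhrnb", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to stratify high-risk neuroblastoma patients into
    ultra-high-risk and high-risk subtypes from immune-gene expression.
    Implements a pan-cancer tumor-specificity filter for immune genes,
    bipartite spectral co-clustering of samples and genes (SVD path plus an
    independent graph-Laplacian oracle path), survival-validated merging of
    clusters into a two-group dichotomy (Kaplan-Meier, log-rank, Cox
    proportional hazards), subtype differential-expression panels with
    cross-cohort overlap statistics (Jaccard index, combinatorial null), and
    a synthetic-cohort simulator with planted checkerboard and survival
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
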
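Package: sigscape
Title: Annotating Sources of Variation in Single-Cell RNA-Seq with Gene
    Signatures and Graph Autocorrelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Functional interpretation of single-cell RNA-seq data without
    requiring a prior clustering. Per-cell gene-signature scores are computed
    with an analytic correction against the moments of a random signature of
    matched size and sign balance.  Signatures are then tested for local
    autocorrelation on a weighted k-nearest-neighbour graph built from a
    latent space or from geodesic distances along a trajectory model, using
    a rank-based Geary's C statistic with an empirical null of grouped
    random signatures and Benjamini-Hochberg correction.  Companion analyses
    include one-vs-all differential signature tests (Wilcoxon / AUROC),
    chi-squared autocorrelation of categorical meta-data with Cramer's V
    effect sizes, correlation of latent components with signatures and
    meta-data, and micro-pooling of transcriptionally similar cells for
    scalability.  Seeded simulators generate clustered and trajectory-shaped
    synthetic datasets with planted signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    methods,
    tools,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
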
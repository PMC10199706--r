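Package: plastiscan
Title: Dissecting Drivers of Transcriptome Plasticity in Factorial RNA-Seq Designs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to determine which experimental variable (developmental
    stage, cultivar, tissue, soil) drives transcriptome variation in a
    complete-crossing bulk RNA-seq design. Implements a three-step
    statistical pipeline: screening of inadequate expression profiles
    (unexpressed, constitutive, outlier genes), k-means co-expression
    clustering with a homogeneity index and variance-explained k selection,
    and per-gene gradient-boosting variable-importance scoring summarised
    per cluster, with top-k rank intersections calling variable-specific
    and variable-shared clusters and principal-component crossing of
    cluster loadings with importances. Also provides TMM normalization
    with a variance-stabilizing transform, a per-stratum one-way soil
    differential-expression screen with FDR, hypergeometric term
    enrichment, promoter best-PWM-score group testing, a TSS-window peak
    filter, a phenology correlation-distance dendrogram, and a fully
    seeded synthetic-data generator with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    Biostrings,
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
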
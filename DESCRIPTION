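Package: basalmir
Title: miRNA Profiling and IHC Marker-Panel Analysis of BRCA1 and
    Sporadic Basal-Like Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a comparative miRNA
    microarray analysis of sporadic versus BRCA1-mutated basal-like breast
    cancers: probe filtering, per-sample shifting, log2 transformation and
    quantile normalization; per-feature ANOVA differential expression with
    the BeadChip as a batch covariate and Benjamini-Hochberg adjustment;
    signature-based unsupervised hierarchical clustering (Pearson
    correlation distance, average linkage); consensus filtering of
    miRNA-target predictions with mRNA cross-referencing for the
    RISC-cleavage subset; and an immunohistochemistry marker-panel
    classifier with prevalence-adjusted predictive values. Seeded
    synthetic-data generators emulate the statistical structure of every
    input so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
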
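Package: reopairs
Title: Rank-Based Gene-Pair Signatures for Binary Tumor Phenotype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discovers within-sample relative expression orderings (REOs) of
    gene pairs that differ between two phenotype groups and assembles them
    into a qualitative majority-vote classifier: Fisher's exact screening
    with Benjamini-Hochberg control, frequency-difference (FD) based
    redundancy removal, an FD-cutoff panel scan and vote-threshold
    optimisation against the harmonic mean of sensitivity and specificity.
    Because the decision rule only compares expression values within a
    sample, the classifier is invariant to any per-sample monotone
    distortion (batch effects, scaling, rank transforms). Includes loaders
    for expression, probe-map and methylation-intensity tables, probe
    collapsing, beta-value computation, evaluation utilities (confusion
    metrics, ROC/AUC with bootstrap intervals, hierarchical-clustering
    concordance, differential methylation, hypergeometric overlap), a
    synthetic-cohort generator with planted gene-pair structure for
    end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
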
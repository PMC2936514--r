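Package: dipscore
Title: Batch-Aware Normalization and Similarity Scoring of Drug-Perturbation
    Expression Compendia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of heterogeneous drug-perturbation expression compendia
    such as the Connectivity Map. Removes production-batch effects by
    mean-centering each probe against the population of drug treatments in its
    batch (rather than against the few vehicle controls), builds detection-call
    aware ranked expression-change profiles and top/bottom optimal signatures
    per drug and cell line, scores drug-drug expression-profile similarity with
    a bidirectional Kolmogorov-Smirnov enrichment statistic (the DIPS score),
    benchmarks pairwise scores against chemical-structure and ATC labels by
    ROC/AUC and partial AUC, and screens drug-target relations for
    drug-induced differential regulation of the target mRNA (feedback loops)
    using per-cell-line Welch tests and a cross-cell-line ANOVA with FDR
    control. A seeded synthetic-compendium generator with full ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
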
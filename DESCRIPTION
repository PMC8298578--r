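Package: cpgrank
Title: Genome-Wide Prioritization of Trait-Associated CpG Sites from
    Array-Based EWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends array-based epigenome-wide association studies (EWAS)
    to every CpG dinucleotide in a genome with a supervised-learning
    pipeline: construction of a positive training set from EWAS summary
    statistics with beta-value-matched negative controls at a 10:1 ratio,
    consensus feature selection across four base learners (regularized
    logistic regression, linear SVM, random forest, gradient-boosted
    trees), nested cross-validated hyperparameter tuning with positive
    upsampling, a soft-voting ensemble, genome-wide CpG scoring with
    log-scale rank scores and empirical p-values, spacing-constrained
    locus selection, annotation and chromatin-state enrichment tests, and
    a complete synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    data.table,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods,
    graphics
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
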
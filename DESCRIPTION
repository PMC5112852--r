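Package: GSReduce
Title: Gene-Set Reduction and Pathway-Guided Sparse Feature Selection
    for Two-Class Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pathway-guided feature selection for two-class (case/control)
    log-scale expression data. Implements the SAM-GS gene-set statistic with
    phenotype-label permutation significance, the gene-set reduction
    algorithm that peels each significant set down to a core subset of genes
    with an SVM-tuned residual-significance cutoff, and a modified pipeline
    in which a SCAD-penalized linear support vector machine performs gene
    selection within the pooled membership of the significant sets. Includes
    the Generalized Brier Score, Belief Confusion Metric, average-precision
    AUPR and misclassification error for classifier evaluation, a
    ground-truth synthetic expression simulator with gene-set-structured
    differential signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, Pathways, Classification, FeatureExtraction,
    Transcriptomics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GSReduce-package.R'
    'RcppExports.R'
    'synthetic.R'
    'samgs.R'
    'reduction.R'
    'scadsvm.R'
    'modified.R'
    'cli.R'
    'io.R'
    'methods.R'
    'metrics.R'
    'utils.R'
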
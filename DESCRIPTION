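Package: igsvm
Title: Hybrid Information-Gain / Support Vector Machine Gene Selection
    for Binary Cancer Classification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage gene selection for two-class gene-expression
    studies. A filter stage ranks genes by information gain on
    MDL-discretized expression (with gain-ratio, reliefF and Pearson
    point-biserial correlation as alternatives); a wrapper stage reduces
    the filtered candidates to a small informative set by recursive
    feature elimination on a linear soft-margin support vector machine;
    the selected genes are assessed by stratified k-fold cross-validation
    of an RBF-kernel SVM. Includes readers for delimited and ARFF
    expression tables, per-gene z-score normalization, a seeded synthetic
    microarray generator with planted class-informative genes, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    foreign,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: Classification, FeatureExtraction, GeneExpression, Microarray
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
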
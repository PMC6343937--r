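Package: phenotrans
Title: Cross-Species Phenotype Translation by Transductive Semi-Supervised Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains classifiers on model-system (mouse) expression cohorts and
    transductively folds unlabeled human samples into training under a
    descending confidence-percentile schedule, yielding predicted human
    phenotypes, predicted human differentially expressed genes
    (Wilcoxon-Mann-Whitney with Benjamini-Hochberg correction), and enriched
    pathways (hypergeometric over-representation over GMT gene sets).
    Includes elastic-net feature selection, four classifier families (KNN,
    SVM, random forest, neural network), precision/recall/F-score and AUC
    benchmarking against truth-phenotype analyses, a linear-model
    meta-analysis of performance across configuration grids, and a synthetic
    paired-cohort generator with planted shared, mouse-only and human-only
    differential expression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    randomForest,
    nnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
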
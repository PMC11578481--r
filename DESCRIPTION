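Package: starnn
Title: Variant-Class-Separated Sparse Neural Networks for Case-Control
    Exome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements STAR-NN, a biologically informed sparse neural
    network that separates rare exonic variants by functional class
    (protein-truncating, possibly damaging missense, mild missense) on a
    per-gene basis for case-control phenotype prediction, together with
    its full upstream pipeline: genotype/sample/variant quality control
    with an exact Hardy-Weinberg test, MPC-based missense tiering and
    rare-variant filtering, gene-by-sample burden aggregation, polygenic
    score computation, univariate feature selection with a four-matrix
    union, baseline models, evaluation metrics over repeated splits, and
    a hypergeometric gene-set overlap statistic. A synthetic cohort
    generator with a logistic liability model makes every stage testable
    without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    e1071,
    jsonlite,
    optparse,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
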
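Package: rebalance
Title: Resampling Methods for Imbalanced Classification with Controlled-Complexity Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how resampling methods behave on imbalanced
    binary classification problems of varying difficulty. Provides a
    simulator of imbalanced domains with controlled complexity, imbalance
    ratio and sample size (a latent correlated-Gaussian model with a
    sigmoid response partitioned into backbone intervals); from-scratch
    implementations of classic oversampling (random, SMOTE, ADASYN,
    borderline-SMOTE), undersampling (random, NearMiss-3, Tomek links,
    CNN, ENN, RENN, All-KNN, OSS, NCR, instance-hardness threshold) and
    hybrid filtering (SMOTE-TL, SMOTE-ENN, SMOTE-IPF) methods; the F3, N2
    and C2 data-complexity measures; precision-recall evaluation with an
    average-precision AUPRC; and a rank-difference protocol with paired
    t-tests for comparing methods across replicated simulated domains.
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
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    e1071,
    nnet,
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
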
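Package: synpair
Title: Fast Screening of Synergic Gene Pairs by Rank Conversion and t-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects gene-gene synergy in binary-phenotype expression data by
    rank-transforming each gene, collapsing every gene pair into a single
    converted feature (sum, diff, mul, sign, or the absolute rank difference
    'abs'), and ranking pairs by a two-sample t-score. Includes a plug-in
    interaction-information estimator as a reference synergy measure, a
    simulator for additive absolute-difference genetic architectures with
    median-binarized phenotypes, and a stratified cross-validation harness
    comparing converted and unconverted feature schemes across seven
    classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
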
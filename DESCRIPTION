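Package: hybridpeel
Title: Hybrid Peeling Imputation and Accuracy Auditing for Pedigreed
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pedigreed livestock populations genotyped with nested
    marker arrays and sparsely sequenced at variable coverage, imputes
    whole-genome allele dosages with two-step hybrid peeling (multi-locus
    iterative peeling for segregation probabilities followed by
    segregation-aware single-locus peeling at every variant), and audits
    imputation accuracy with leave-one-out validation, regression-tree
    factor analysis, and error-injection stress tests. Includes a
    sequencing-budget allocator that targets top parents, focal ancestors
    and under-sequenced pedigree branches, and Mendelian-consistency
    quality control with automatic pedigree repair.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
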
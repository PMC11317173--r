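Package: declone
Title: Clonal Decomposition of Non-Tumor Bulk Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes bulk sequencing of diploid, copy-number-neutral
    (non-tumor) samples into individual subclones, ancestral superclones and
    a false-variant cluster. Variant allele frequencies are modelled with a
    modified expectation-maximization mixture of beta-binomial clusters plus
    a zero-centroid error cluster under a binomial sequencing-error model;
    candidate solutions are constrained so that individual-clone centroids
    sum to 0.5 per sample (heterozygous, total cellular prevalence one) and
    superclones obey the sum rule. The clone number is selected with a
    gap-statistic criterion and fuzzy membership is retained when cluster
    posteriors overlap. Includes a simulator for benchmark datasets with
    Dirichlet clone proportions and reverse-sigmoid false-variant allele
    frequencies, and scoring utilities (clone-number RMSE, adjusted Rand
    index, best-injection membership score).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
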
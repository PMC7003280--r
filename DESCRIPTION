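Package: herbminer
Title: Prescription Pattern Mining for Chinese Herbal Formulae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for mining co-prescription patterns in
    Chinese herbal medicine records: terminology standardization against a
    herb knowledge base, frequency and attribute (property, taste, meridian,
    action-category) profiling, level-wise Apriori association-rule mining
    with support/confidence/lift, agglomerative hierarchical clustering of
    high-frequency herbs on binary prescription incidence, and extraction of
    the multiscale (disparity-filter) backbone of the herb co-prescription
    network. Includes seeded synthetic-prescription generators with planted
    template structure and an exact-count fixture builder for validating
    every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    igraph,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
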
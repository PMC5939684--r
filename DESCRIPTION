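Package: mirlag
Title: Time-Lagged miRNA-mRNA Inverse-Expression Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating miRNA and mRNA
    expression time courses in the rd10 mouse model of retinitis pigmentosa.
    Identifies differentially expressed miRNAs with signed fold changes and
    Benjamini-Hochberg adjusted Welch tests, classifies them by temporal
    onset relative to photoreceptor apoptosis (pre-onset group A versus
    post-onset group B), links them to inversely expressed predicted target
    mRNAs in time-indexed bipartite networks, runs hypergeometric
    over-representation analysis of the inversely expressed gene set, and
    validates candidates with a multi-reference delta-delta-Ct scheme with
    reference-gene stability selection. A seeded synthetic-data generator
    emulates the two-genotype, three-timepoint study design with planted
    ground truth so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
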
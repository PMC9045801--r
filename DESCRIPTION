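Package: fwdfungi
Title: Fungal Community Succession on Fine Woody Debris
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fungal community succession on fine woody
    debris (FWD) under a tree-species by canopy-openness by time factorial
    design. Covers OTU-table preparation (species-level aggregation,
    rarefaction, Hellinger transformation, abundance filters, guild
    profiles), per-sample diversity estimates (richness, Chao1, Shannon,
    Pielou evenness), per-taxon succession statistics (tree and canopy
    specificity with specialist classification, abundance-weighted
    succession time, 90% occurrence duration), permutation multivariate
    statistics written from scratch (PERMANOVA, Mantel, vector fitting,
    variation partitioning, non-metric multidimensional scaling with
    Kruskal stress), deadwood stock estimation from census plots, and a
    synthetic-data generator that emulates the factorial study design with
    known per-taxon ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    vegan
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
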
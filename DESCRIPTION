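Package: oceanet
Title: Community Assembly, Co-Occurrence Networks and Keystone-Taxon
    Robustness for Marine Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream ecological inference for amplicon-based microbiome
    surveys of contrasting habitats (e.g. marine sediment versus seawater):
    rarefaction and abundance filtering of OTU tables; alpha diversity,
    Bray-Curtis ordination, ANOSIM and SES.MNTD phylogenetic null models;
    Sloan neutral community model fitting with a binomial-sampling
    competitor, bootstrap AIC comparison and a stochastic-to-deterministic
    taxon ratio; abundance-occupancy core-microbiome selection scored by
    cumulative contribution to beta diversity; Spearman/Benjamini-Hochberg
    thresholded co-occurrence networks with global and node-level topology;
    and a keystone-taxon (e.g. sulfate-reducing bacteria) node-removal
    robustness simulation scored by natural connectivity. Includes seeded
    synthetic-data generators (neutral communities with known migration
    rate, block/hub-structured correlation tables, pure-birth phylogenies)
    so every stage is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    biomformat,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
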
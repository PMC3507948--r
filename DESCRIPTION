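Package: gainscan
Title: Detecting the Origin of New Protein Functions in Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for localizing the evolutionary origin of a
    derived protein function within a duplicated gene family, built around the
    vertebrate visual-cycle enzymes RPE65 and LRAT as the motivating case.
    Provides distance-based phylogenetics (p and Poisson-corrected protein
    distances, neighbor-joining with column-bootstrap support), lineage
    rate-per-time calibration, a permutation test for type-II (cluster-specific)
    functional divergence between two clades with a windowed hypergeometric
    critical-residue enrichment statistic, diagnostic-residue scorecards,
    in-silico tryptic digestion with peptide mass fingerprinting against
    MALDI-TOF centroid peak lists, reciprocal-best-hit orthology calls from
    tabular similarity hits, and seeded synthetic-data generators that emulate
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
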
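Package: magqc
Title: Completeness and Contamination Estimation for Eukaryotic
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the quality of (meta)genome-assembled eukaryotic
    genomes from single copy marker genes (SCMGs). Builds a database of
    clade-specific marker sets from profile-HMM annotations of reference
    proteomes (per-profile bit-score threshold calibration, single-copy
    prevalence mining over a reference tree, and a greedy overlapping
    reference set for initial placement), dynamically selects the most
    specific applicable set for a query via phylogenetic placements
    (lowest common ancestor with ascent to the highest set-bearing
    ancestor), and reports completeness, contamination, consensus
    lineage, the unassessed genome fraction, and a marker-uniformity
    diagnostic. Also generates fragmented and contaminated benchmark
    genomes with full truth labels for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
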
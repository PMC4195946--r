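Package: hervnahr
Title: Genome-Wide Prediction and Analysis of HERV-Mediated Non-Allelic
    Homologous Recombination
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts pairs of human endogenous retrovirus (HERV) elements
    capable of mediating non-allelic homologous recombination (NAHR) by
    screening repeat annotations for directly oriented, high-identity,
    long-alignment element pairs; condenses predicted pairs into
    genome-instability susceptibility regions; cross-references copy-number
    variant (CNV) calls with probe-bounded breakpoint-uncertainty intervals
    against predicted pairs; localizes recombination crossovers between
    informative cis-morphisms (paralogous sequence variants) from junction
    sequences; tests breakpoint clustering with a Monte-Carlo statistic
    conditioned on local sequence identity; and scans for PRDM9
    recombination hotspot motifs with Poisson and rank-based enrichment
    tests. A synthetic-genome simulator generates all fixture inputs with
    recorded ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
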
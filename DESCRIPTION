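Package: olisim
Title: Fold-or-Hold Selection of Self-Priming DNA Hairpins: Simulation and
    Sequence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vitro experimental evolution with populations of
    short self-priming DNA hairpins ("Oli" molecules) under fold-or-hold
    selection. Provides a two-state thermodynamic model of 3'-terminal
    hairpin stems and self-priming, a full serial-transfer simulator
    (self-priming, primer-limited mutagenic PCR with exponential versus
    linear growth, in silico restriction digestion, bottleneck transfer,
    sequencing), read preparation (primer filtering, reverse-complement
    dereplication, restriction trimming, digestion-escape analysis),
    threshold clustering of unique sequences with exact edit distances,
    genealogy-network reconstruction across sampled transfers by
    Smith-Waterman closest-match assignment, and summary statistics
    (extinction tables, qPCR relative-slope fitness, fold-fraction
    estimation, genome-length distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
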
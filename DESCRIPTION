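Package: evoscape
Title: Fitness Landscapes, Epistasis, and Mutation Statistics for
    Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of microbial evolution experiments in
    continuous culture: selection-coefficient estimation from pairwise
    competition time series (linear-phase selection, regression confidence
    intervals, wild-type normalization, ANCOVA), epistasis quantification
    with error propagation and classification of interaction types up to
    reciprocal sign epistasis, empirical fitness-landscape analysis (local
    and global optima, selectively accessible mutational paths,
    deterministic selection-mutation dynamics), heuristic post-caller
    SNP/indel filtering of ancestor/evolved clone pairs, copy-number
    estimation of tandem amplifications from read-depth ratios and qPCR
    delta-delta-Ct, and neutral-mutation Poisson statistics including
    nonsense-capacity codon scanning.  A synthetic-data generator
    reproduces the statistical structure of every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
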
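Package: trmcseq
Title: Calling N4-Acetylcytidine Sites on tRNA from Reduction and
    Misincorporation Sequencing
Version: 0.1.0
Authors@R:
    person("TRMC-seq", "Maintainers", email = "trmcseq@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for reduction-and-misincorporation sequencing
    of tRNA N4-acetylcytidine (ac4C). Borohydride reduction converts ac4C
    into a base that reverse transcriptase misreads, leaving a C-to-T
    misincorporation signature in sequencing reads. The package loads and
    normalizes mature tRNA/rRNA references, aligns reads with a strict
    mismatch cap, builds per-position base-count pileups, and calls ac4C
    sites from a three-condition chemistry design (reduced, deacetylated,
    mock) with exact tests and false-discovery-rate control. It also
    quantifies tRNA abundance changes, and computes downstream translation
    readouts: ribosome P/A-site assignment, basal-normalized codon
    occupancy, translation efficiency, and codon-frequency bias across
    translation-efficiency classes. A fully seeded read simulator embeds
    the reduction chemistry's signature so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
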
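Package: tolipscan
Title: Proteome Screening for Short Toxin-Like Proteins
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein FASTA collections for short toxin-like proteins
    (TOLIPs): short, secreted, cysteine-rich endogenous proteins that resemble
    animal toxins outside any venom context. The pipeline filters a proteome to
    sequences shorter than a length cutoff, extracts cysteine-spacing, charge,
    polarity-profile and composition features, scores sequences with a boosted
    decision-stump ensemble whose member agreement maps onto four confidence
    tiers (N/P1/P2/P3), and annotates candidates with a rule-based
    signal-peptide call, Ly-6/uPAR (LU) three-finger cysteine-scaffold matches,
    and chromosomal paralog-cluster membership from BED/TSV gene tables. A
    seeded synthetic-data module generates proteomes and gene tables with
    planted structure so the whole screen is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
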
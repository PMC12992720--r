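Package: ervscape
Title: Endogenous Retrovirus Landscape Analysis for Drosophila LTR Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of insect endogenous
    retroviruses (iERVs) and other LTR retrotransposons from consensus
    libraries and genomic insertion panels: piRNA-cluster silencing
    potential as antisense k-mer coverage of consensus sequences,
    insertion dating from pairwise 5'/3' LTR divergence (Jukes-Cantor
    corrected, T = K/2r), ORF-integrity classification with detection of
    inactivating frameshifts and premature stop codons, env-F remnant
    discovery by translated local alignment, LTR-variant typing with
    recombination breakpoint calling from diagnostic alignment sites, and
    per-column alignment frequency profiles. Includes a deterministic
    synthetic-data generator with ground truth so every analysis stage can
    be validated offline, plus a file-based pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
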
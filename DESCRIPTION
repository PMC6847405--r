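Package: sdscan
Title: Shine-Dalgarno Usage and Anti-SD Site Preference from Genomes and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising Shine-Dalgarno (SD) mediated translation
    initiation in bacteria, cyanophages and chloroplasts. Calls the mature 16S
    rRNA 3' terminus (the anti-SD tail) from RNA-Seq read-end pileups, scans
    30-nt upstream windows for >=4-nt SD/anti-SD duplexes with the D_toStart
    spacing statistic, tests site-specific anti-SD usage against a
    composition-preserving shuffled null with an upper-tailed Z-test,
    classifies genes as SD-facilitated or SD-independent, and contrasts
    protein abundance, protein-per-transcript (FPKM-normalised) and 5'-UTR
    minimum free energy between the two classes. Includes a synthetic-data
    generator with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: ViennaRNA (RNAfold on the PATH) for minimum-free-energy
    computations
Config/testthat/edition: 3
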
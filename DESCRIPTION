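Package: carpassay
Title: Targeted Cytochrome-b eDNA Metabarcoding Assay for Invasive Carps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a diagnostic cytochrome-b haplotype reference panel for
    silver carp (Hypophthalmichthys molitrix) and relatives from a variant-key
    table, performs in-silico PCR with IUPAC degenerate primers, and processes
    paired-end amplicon reads through spacer/primer verification, overlap
    merging, dereplication into amplicon sequence variants (ASVs), Poisson-model
    denoising, chimera removal, positive-control calibration of an erroneous-ASV
    cutoff, and species/haplotype assignment with flagging of below-cutoff
    divergent detections. Includes a seeded read simulator with truth tables so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
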
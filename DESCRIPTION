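Package: crispantquant
Title: Editing-Outcome Quantification for CRISPR/Cas9 F0 Crispant Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies CRISPR/Cas9 editing outcomes from deep amplicon
    sequencing of mosaic F0 animals (crispants), with duplicated-genome
    loci in mind. Locates protospacer/PAM target sites on reference
    amplicons, trims and merges MiSeq-style paired-end reads, aligns
    reads with a deterministic glocal affine-gap aligner, classifies
    each read as wild-type, in-frame or frameshift from the net indel
    length in a quantification window, and summarizes per-individual,
    per-tissue and cohort editing fractions. Includes a mosaic-crispant
    read simulator with ground-truth allele spectra for parameter-recovery
    testing, and efficiency-corrected relative expression analysis
    (Pfaffl-style delta-delta-Ct) with exact Mann-Whitney U comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
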
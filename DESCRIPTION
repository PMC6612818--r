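Package: pecr
Title: Barcode-Free PCR Error Correction for Circulating-Free DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects PCR errors in aligned paired-end sequencing reads from
    heavily amplified libraries (circulating-free DNA, single-cell) without
    molecular barcodes. Read pairs sharing unclipped 5' coordinates and
    orientation are grouped into PCR-duplicate families; high-depth families
    are collapsed to a quality-aware per-column consensus, and the k-mers
    corrected in the process build a catalogue of recurrent error patterns
    ("error k-mers") that is used to flag probable systematic errors in
    singleton and low-depth reads by downgrading base qualities ("intrinsic
    polishing"). Surviving reads are realigned with a deterministic affine-gap
    Smith-Waterman and written back to BAM. Includes the analytic
    birthday-paradox model for the probability that two distinct cfDNA
    fragments collide at identical start and end coordinates, and a
    truth-annotated read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
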
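Package: cnvseqr
Title: Low-Pass Read-Depth CNV Calling for Products-of-Conception Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number analysis of low-coverage (~1x) whole-genome
    sequencing read depth in 10 kb bins, as used for chromosomal screening
    of miscarriage (products-of-conception) tissue. Implements GC-stratified
    depth correction, reference-panel R/Z copy-number statistics, circular
    binary segmentation with permutation significance, a five-state Gaussian
    hidden Markov model, whole-chromosome and mosaic aneuploidy detection
    with ISCN-style karyotype reporting, a five-tier (ACMG-style) CNV
    classification cascade against local annotation tables, cohort
    contingency statistics, and hypergeometric gene-set over-representation.
    A synthetic-data generator with known ground-truth karyotypes makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
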
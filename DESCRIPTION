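Package: plasmacnv
Title: Somatic Copy-Number Analysis from Shallow Whole-Genome Plasma Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for somatic copy-number alteration (SCNA) analysis of
    shallow whole-genome sequencing of cell-free DNA (plasma-Seq): read-count
    binning on an equal-mappability grid, GC-bias correction by local
    regression, normalization against a non-tumour control panel, native
    circular binary segmentation with permutation testing, gain/loss calling
    at +/-0.2 log2 thresholds, a 3-SD control-based aberrance classifier,
    rule-based focal amplification/deletion calling with driver-gene
    annotation, serial-sample differential copy-number analysis with
    tumour-content ratio fitting, hierarchical profile clustering, and
    cohort-level statistics. A synthetic ctDNA data generator with known
    copy-number truth (GC bias, Poisson counts at ~0.1x coverage, tumour
    fraction, dilution series, serial scenarios) makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    Rsamtools
Config/testthat/edition: 3
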
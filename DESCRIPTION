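Package: starrscore
Title: Allelic Activity Analysis for Barcoded STARR-Seq Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for massively parallel reporter assays
    (barcoded STARR-seq) that test regulatory variants in both allelic
    states. Covers oligo library design from a variant table and reference
    genome, exact-match read assignment and barcode counting, per-barcode
    log2 RNA/DNA activity scores with the standard depth filters,
    Mann-Whitney differential-allele testing with Benjamini-Hochberg
    correction, activity-quintile peak-overlap enrichment, allelic
    expression imbalance from paired DNA/cDNA amplicon counts, and a
    cross-validated lasso model of enhancer activity. Includes a synthetic
    data generator that emulates the barcode-level count structure of a
    replicated MPRA for calibration and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
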
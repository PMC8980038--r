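Package: atacburst
Title: Differential Chromatin Accessibility from Binned ATAC Fragment Ends
    and Spike-Train Burst Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired-end ATAC-seq fragment records stratified by
    Tn5 fragment-length class (subnucleosomal, nucleosomal, poly-nucleosomal),
    with read-extremity counting over a fixed-width genome binning, library
    quality filtering, median-of-ratios count normalization, per-interval
    fold changes with exact two-sided Mann-Whitney tests between genotype
    groups, and the enhanced/repressed accessibility ratio computed over
    sliding windows of p-ranked intervals to detect genome-wide directional
    shifts in accessibility. Also provides interval annotation against genes,
    gene flanks and candidate cis-regulatory elements, in vivo spike-train
    burst segmentation with windowed firing-rate and percent-spikes-within-
    burst metrics, and a synthetic-data generator with planted accessibility
    effects and known burst composition for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    optparse
Config/testthat/edition: 3
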
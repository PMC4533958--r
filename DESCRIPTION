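Package: smallRNAtlas
Title: Small RNA Population Profiling and Negative-Binomial Differential
    Expression for Germ Cell Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling small non-coding RNA populations from aligned
    small RNA-seq reads: read-length and base-composition signatures (5'U, 5'G,
    position-10 A fractions and positional information content), strand-specific
    merging of read alignments into small RNA contigs as piRNA-precursor
    proxies, annotation-based read classification with tRNA-fragment typing,
    a negative-binomial exact test with median-of-ratios normalization,
    pooled dispersion estimation (maximum sharing; parametric or local fit)
    and a variance-stabilizing transformation, hierarchical clustering and
    volcano/heatmap table export, and delta-delta-CT qPCR quantification.
    Includes a synthetic-data generator that emulates the small RNA read
    populations of normal testis and testicular germ cell tumor tissue for
    end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
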
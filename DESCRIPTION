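Package: kiteval
Title: Quality Evaluation of Exome Capture Sequencing Kits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structured methodology for benchmarking exome capture kits
    against clinical diagnostic quality standards. Provides interval algebra
    over capture designs (merge, multi-way intersection, partition into
    coding/UTR/intron, panel construction with exon padding), per-sample
    alignment metrics (insert size, coordinate-based duplicate marking,
    on-target rate, depth of coverage), coverage uniformity statistics
    (fold-80 base penalty, evenness score), seeded read-pair downsampling
    for coverage-efficiency curves across sequencing efforts, Ts/Tv variant
    quality, run-level sequencer QC with instrument-aware thresholds, and a
    kit-comparison report. A synthetic-data module simulates alignments,
    reads and variants with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
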
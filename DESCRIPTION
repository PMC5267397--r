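Package: qchromatin
Title: Chromatin Occupancy and Transcriptome Comparison Between Growing and
    Quiescent Yeast Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare histone-methylation and RNA polymerase II
    occupancy, and transcript content, between exponentially growing (log)
    and quiescent (Q) yeast cells. Provides per-gene enrichment scoring from
    binned IP/input signal tracks, marked-gene calling and log/Q/common
    partitioning, TSS/TES-anchored metagene profiles, transcript-length
    sorted occupancy matrices, genome-wide Spearman co-occupancy analysis
    with 4-way Venn partitioning and Fisher's exact tests, divergent
    intergenic-region classification, and two-state transcriptome set
    comparisons. A synthetic-data generator with known ground truth makes
    every stage testable without external array or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
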
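Package: peakshift
Title: Differential Histone-Mark Peak Detection, Motif Vectorization and
    Cluster-Linked Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for two-condition ChIP-seq coverage
    analysis built around a landmark-based peak caller: depth tracks are
    smoothed with a moving average, candidate peaks are enumerated from
    minima, maxima and slope-change landmarks and filtered on
    baseline-relative maximum and integrated excess depth.  Peaks are
    classified as condition-enriched (Peaks_2.0), condition-depleted
    (Peaks_0.5) or unchanged from group mean depths, converted to k-mer
    motif occurrence-frequency vectors, clustered by k-means, and
    group-specific clusters are linked to fold-change-filtered gene
    expression within a genomic distance window.  A synthetic-data
    generator with planted peaks, motifs and regulated genes makes every
    stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
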
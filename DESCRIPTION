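Package: chromdiverge
Title: Comparative Chromatin Analysis of Expression-Coupled Histone Marks in Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparing genome-wide H3K9ac and H3K4me3 landscapes
    within and between closely related budding yeast species. Builds
    base-resolution coverage tracks from stranded aligned-read positions
    (strand cross-correlation fragment-length estimation, total-count
    normalization, histone H3 occupancy normalization), extracts gene-anchored
    binned profiles and nucleosome-level signals, computes the per-gene
    acetylation/methylation disparity statistic with hypergeometric gene-class
    enrichment, and classifies interspecies divergence of modifications and
    expression at orthologous genes. A synthetic-data module generates two
    diverged species with planted modification landscapes so the full analysis
    runs offline with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
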
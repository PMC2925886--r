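Package: exonmark
Title: Exon-Intron Marking Analysis for ChIP-chip and ChIP-seq Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying preferential association of histone
    modifications, RNA polymerase II and nucleosomes with exons versus
    introns ("exon-intron marking") from tiled two-channel ChIP-chip
    arrays and short-read ChIP-seq. Implements the full tile-level
    normalization chain (background-corrected enrichment ratios,
    replicate composites, histone-density and IgG correction, sequential
    ChIP control subtraction, log2 centred Z-scores), canonical versus
    alternative exon classification from multi-transcript gene models,
    midpoint assignment of tiles and 200-bp read bins to gene features,
    consensus exon-intron metaprofiles, expression stratification, a
    coordinate-randomization bootstrap null with empirical and
    parametric p-values, adjacent exon-intron Welch t-tests, and a
    synthetic-data generator that plants known effect sizes so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
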
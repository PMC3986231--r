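Package: dhcmeta
Title: Metabolic Network-Guided Meta-Analysis of Dehalococcoides
    mccartyi Microarray Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the meta-analysis of absolute-intensity microarray
    transcriptomes of the organohalide-respiring bacterium Dehalococcoides
    mccartyi, guided by its pan-genome-scale metabolic network. Provides
    species-consensus probe assignment from alignment hit tables,
    intensity-threshold on/off transcription calling with proteomic-evidence
    cross-tabulation, row z-score normalization and sample-level principal
    component analysis, quality-threshold (QT) clustering of expression
    profiles under a Spearman rank-correlation distance, hypergeometric
    functional-category enrichment of clusters, and comparative operon
    prediction from intergenic distance and a conserved-adjacency barcode
    using a naive Bayes model. A seed-deterministic synthetic-data generator
    emulates realistic array and genome data with known ground truth so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    methods,
    ape,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
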
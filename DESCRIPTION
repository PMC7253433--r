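Package: rg4tools
Title: RNA G-Quadruplex Prediction, CLIP Enrichment, and RNA Pull-Down
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the protein machinery that recognizes RNA
    G-quadruplex (RG4) forming G-rich sequences. Implements QGRS-style RG4
    motif prediction and G-scoring on annotated transcripts
    (5'UTR/CDS/3'UTR), enrichment statistics for CLIP binding sites against
    a resampled random-site background (Fisher exact test, density per Mb,
    fraction of RG4s bound), label-free RNA pull-down proteomics
    differential-binding analysis (downshifted-Gaussian imputation of
    missing-not-at-random values, paired sign-flip permutation FDR,
    RG4-BP/G-rich-BP classification by WT/7dG ratio), closed-form assay
    quantifications (2^-ddCt expression, RIP enrichment, polysome
    translational efficiency, reporter ratios, clonogenic survival), and
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
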
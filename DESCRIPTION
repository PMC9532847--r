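Package: splicescape
Title: Quantifying How a Transcription Factor Reshapes an Alternative
    Splicing Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for relating transcription-factor (TF)
    expression to genome-wide alternative splicing in bulk tumor
    transcriptomes. Implements relative-importance (LMG) covariance
    modelling of splicing-related gene expression, a dual nonparametric
    differential-splicing caller on percent-spliced-in (PSI) values with
    shuffle-based empirical nulls and down-sampling success rates, mixed
    versus dominant isoform trajectory analysis with Monte Carlo sign
    nulls, annotation of nonsense-mediated-decay determinant exons,
    position-specific tetramer enrichment with motif-to-RBP Matching
    Scores built on Bhattacharyya map similarity, S-statistic and
    per-event survival stratification with Cox models and maximally
    selected cutpoints, and an in-silico tumor-purity mixing simulation.
    A seeded synthetic-data generator emulates the statistical structure
    of the study inputs so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    caret,
    survival,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
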
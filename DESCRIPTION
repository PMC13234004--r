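Package: tfbinder
Title: Multi-Label Prediction of Transcription Factor Family Binding from DNA Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and explains multi-label convolutional neural network
    classifiers that map fixed-length genomic DNA windows to transcription
    factor (TF) family binding profiles, in the style of family-level DAP-seq
    modelling. Provides window labelling from peak files with a coverage rule,
    chromosome-held-out cross-validation, class-weighted and offset-augmented
    training for imbalanced families, shuffle-sequence baselines,
    attribution-based discovery of interaction predictive motifs (IPMs),
    regulatory-syntax statistics (offset independence, weighted co-occurrence,
    IPM context importance, co-enrichment networks), gene regulatory-profile
    clustering with enrichment and co-expression permutation tests, variant
    effect prediction with an in-silico control-mutation null, and annotation
    of untargeted footprint peaks with condition-response classification.
    Includes a fully specified synthetic-genome generator with planted motifs
    so every component is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    glmnet,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
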
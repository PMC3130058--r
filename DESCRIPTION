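Package: TFIpred
Title: Sequence-Based Prediction of Transcription Factor Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts physical interactions between human transcription
    factors from primary sequence alone. Protein sequences are split into
    N-terminal, middle and C-terminal segments (20/60/20 of length) and
    summarised by per-segment means of amino-acid physicochemical scales
    taken from an AAIndex1 property table; a pair of factors is encoded as
    the molecular-weight-ordered concatenation of the two member vectors.
    Classification uses quadratic discriminant analysis with wrapper
    forward feature selection under preserved stratified cross-validation
    folds. Includes construction of the three random negative-pair classes
    (absolute, partial and PPI negatives), PSI-MI interaction-type
    filtering, a local-alignment sequence-identity redundancy filter for
    the positive set, confusion-matrix performance reporting, and a
    synthetic-study generator that plants known composition-level class
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
biocViews: Classification, Proteomics, FeatureExtraction,
    NetworkInference, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
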
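Package: lgct
Title: Local-Global Convolutional Transformer for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of motor-imagery EEG trials with a three-branch
    convolutional transformer. Each frequency-band branch combines a temporal
    block fusing a 1-D CNN with a windowed (local) self-attention encoder, a
    spatial block contrasting all-channel and hemisphere-difference depthwise
    filters, and a densely connected CNN + global-transformer unit. Includes
    band-pass preprocessing, within- and cross-session evaluation protocols,
    ablation variants, a synthetic lateralized-EEG generator with controllable
    event-related desynchronization, EDF and flat-binary trial input, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
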
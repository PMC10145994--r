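Package: mieegnet
Title: Six-Class Motor-Imagery EEG Classification with a Compact
    Convolutional Network and Discriminant-Channel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for six-class motor-imagery
    electroencephalography (EEG) classification in the HaLT (hand, leg,
    tongue) interaction paradigm. Reads 19-channel, 200 Hz recordings in
    the HaLT MAT-file layout, epochs them into fixed 170-sample labelled
    trials, and classifies them with a compact convolutional network of
    the EEGNet family (temporal, depthwise and separable convolutions
    with batch normalisation, ELU activations and average pooling),
    trained with the Nadam optimiser and an optional triangular cyclical
    learning-rate schedule. Two discriminant-channel selection strategies
    are provided: accuracy-rating-based selection (ARbC), which ranks
    electrodes by single-channel classifier cross-validation accuracy,
    and a channels-mutual-information-based approach (CMIbA) built on
    histogram estimates of Shannon entropy and Kullback-Leibler
    divergence. Includes a stratified k-fold cross-validation harness
    with confusion matrices, a synthetic-session generator with planted
    informative channels for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
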
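Package: midecode
Title: Motor-Imagery EEG Decoding with Spectral and Directed-Connectivity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pairwise classification of
    motor-execution, motor-imagery, observation and rest conditions from
    multichannel EEG. Provides a synthetic high-density EEG study generator
    with planted sensorimotor band-power effects, IIR preprocessing and
    trial segmentation, FFT band-power and full-frequency Directed Transfer
    Function (ffDTF) connectivity features from multivariate autoregressive
    models fitted with a Vieira-Morf lattice estimator, nested
    cross-validated greedy feature-subset selection with linear support
    vector machines, maximum-chance significance statistics, and summary
    tables over a full experimental grid of montages, condition pairs and
    feature kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
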
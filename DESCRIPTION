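Package: drowsinet
Title: Multi-Timescale Drowsiness Characterization from Eyelid-Distance
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize drowsiness at four timescales (5, 15, 30
    and 60 seconds) from one-minute sequences of eyelid distances sampled at
    30 Hz. Provides a ground-truth pipeline based on reaction times from
    psychomotor vigilance tasks (inter-subject normalization of reaction
    speeds, windowed harmonic-mean "median RTs", ternary drowsiness labels),
    a temporal convolutional network with sigmoid-weighted attention pooling
    and a shared multi-timescale context, a blink-segmentation and ocular-
    feature proxy baseline with linear max-margin classifiers, a
    leave-one-subject-out evaluation harness, and a synthetic PVT-session
    simulator that couples blink dynamics and reaction speeds through a
    latent drowsiness process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
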
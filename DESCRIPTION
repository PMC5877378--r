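Package: eegemotion
Title: Self-Induced Emotion Recognition from EEG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for EEG-based recognition of self-induced
    (recall-elicited) versus movie-induced emotion. Simulates multichannel
    EEG with the six-emotion, dual-paradigm trial structure of a 30-subject
    movie/recall protocol; preprocesses recordings (0.1-80 Hz zero-phase
    band-pass, ICA-based ocular artifact removal, baseline stripping, 2 s /
    50 percent overlap epoching); extracts a 366-dimensional feature vector
    per epoch (differential entropy of five STFT frequency bands plus the
    log mean absolute first difference of the first intrinsic mode function
    from empirical mode decomposition, per channel); ranks features by
    minimal-redundancy-maximal-relevance mutual information; classifies with
    a linear support vector machine under leave-one-clip-out, six-class and
    cross-paradigm protocols; and summarizes per-class neural patterns as
    scalp topographies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
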
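Package: emorec
Title: EEG/ECG Emotion Recognition Under Expanding Negative-Emotion Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how enlarging the
    set of negative emotion categories degrades physiological emotion
    recognition.  Generates synthetic annotator rating tables, multichannel
    EEG and single-lead ECG with controllable between-negative-emotion
    overlap; performs annotator outlier rejection and inter-rater agreement
    statistics (Krippendorff's alpha, Cohen's kappa); extracts differential
    entropy EEG band features and a 19-feature heart-rate-variability
    battery (time, geometric, spectral, detrended fluctuation analysis,
    approximate entropy, Poincare); classifies emotions with a linear
    support vector machine under block cross-validation; and screens
    features with volcano-plot differential statistics along the valence
    and arousal dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
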
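Package: eegpref
Title: EEG-Based Consumer Preference Recognition with Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multi-channel EEG epochs with a controllable
    like/dislike frontal band-power asymmetry, extracts power spectral
    density (PSD) feature blocks (full-epoch periodogram, Morlet wavelet
    average power, Hann spectrogram, cross-channel aggregates) and ten
    frontal preference indices (approach/withdrawal, valence, choice and
    effort scores), ranks features with four selection algorithms (minimum
    redundancy maximum relevance, ReliefF, random-forest recursive feature
    elimination, principal component analysis) plus random-forest impurity
    importance, and benchmarks five classifiers (linear discriminant
    analysis, radial-kernel support vector machine, random forest,
    1-nearest neighbour, and a hinge-loss multilayer perceptron) on a
    stratified holdout split with leakage-safe selector fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    MASS,
    class,
    e1071,
    ranger,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
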
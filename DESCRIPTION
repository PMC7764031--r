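Package: eegrca
Title: Correlation-Based Band-Electrode Selection and Emotion
    Classification for Multi-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes multi-channel EEG trials into the four classical
    analysis bands (theta, alpha, beta, gamma), builds per-second
    band-power features for every band-electrode combination, selects the
    least mutually correlated feature subset with an unsupervised reversed
    correlation greedy algorithm, and evaluates valence/arousal emotion
    classification with a Gaussian-kernel support vector machine under
    stratified k-fold cross-validation with in-fold selection. Includes a
    seeded synthetic EEG generator with planted band-power class effects
    and engineered channel redundancy, fixed literature channel sets for
    benchmarking, readers and writers for an HDF5 trial container and for
    EDF recordings, and a command-line pipeline producing reproducible
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
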
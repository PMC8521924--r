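Package: eegsweep
Title: Unsupervised EEG Artifact Detection and Self-Supervised Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully unsupervised pipeline for cleaning epoched
    multichannel EEG. Epochs are summarised by a bank of 58 quantitative-EEG
    features (complexity, continuity and connectivity families), scored for
    anomalousness by an ensemble of unsupervised outlier detectors (HBOS, LOF,
    ABOD, one-class SVM, PCA/autoencoder/VAE reconstruction, and a locally
    selective LSCP combiner), and flagged by a user-supplied contamination
    estimate. Flagged epochs are repaired by a self-supervised gap-interpolation
    stage: one small encoder-decoder network per missing-sample offset, trained
    on clean epochs only, splices predictions into the most deviant segment of
    each artifact epoch. Includes an EDF reader, a seeded synthetic-EEG
    generator with ground-truth artifact injection (blink, muscle, electrode
    pop, drift), agreement metrics (F-score, Cohen's kappa), a downstream
    classifier probe, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
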
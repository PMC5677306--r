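Package: miwave
Title: Wavelet Feature Fusion and GMM-Supervector Reduction for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-class motor-imagery EEG classification pipeline: Morlet
    continuous-wavelet log band-power features (1 Hz bins, 6-30 Hz), db4
    discrete-wavelet sub-band statistics over theta/mu/beta rhythms, PCA
    fusion of the combined 96-dimensional feature vector at 98% retained
    variance, per-class diagonal-covariance Gaussian-mixture training-set
    reduction ("GMM supervectors"), and RBF-kernel SVM classification with
    10-fold cross-validated grid search. Includes a seeded generator of
    synthetic event-related-desynchronization trials so every stage is
    testable without external recordings, plus readers and writers for a
    plain-text columnar trial format and minimal EDF support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
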
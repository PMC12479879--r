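Package: eodsep
Title: Unsupervised Separation of Electric Organ Discharges from Paired
    Pulse-Type Electric Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection, feature extraction and unsupervised separation of
    electric organ discharges (EODs) recorded from two freely swimming
    pulse-type weakly electric fish (Gnathonemus petersii) on a two-channel
    electrode pair. Implements threshold detection with refractory
    suppression, 31-sample waveform extraction with polarity
    canonicalization, Morse-wavelet scalogram features, t-SNE embedding with
    average-linkage hierarchical clustering into two clusters, silhouette and
    CDbw cluster-quality indices, supervised baselines (scalogram template
    correlation and an RBF-SVM), evaluation metrics (accuracy, Matthews
    correlation coefficient), EOD sonification (pulse-wise bursts and
    IPI-driven frequency modulation), and a ground-truth-labelled synthetic
    dyad simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
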
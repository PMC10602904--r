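Package: flowcoh
Title: Stimulus-Brain Coherence Analysis for Video-Evoked EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies frequency-resolved coherence between the optical-flow
    magnitude timeseries of a video stimulus and multichannel EEG. Implements
    dense optical flow extraction, the standard EEG preprocessing chain
    (mastoid re-referencing, zero-phase Butterworth band-pass, regression-based
    ocular correction, amplitude artifact rejection, epoching), a narrowband
    IIR filter bank with lagged-correlation peak extraction, region-by-frequency
    feature matrices, information-based univariate feature ranking, and a
    cross-validated brain-state classifier battery. A synthetic-data module
    generates videos, optical-flow signals, and EEG with known embedded
    entrainment so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    MASS,
    class,
    nnet,
    rpart,
    e1071,
    randomForest,
    ranger,
    xgboost,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
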
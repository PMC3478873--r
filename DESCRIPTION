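Package: lhmmecg
Title: Layered Hidden Markov Models for Wearable ECG Arrhythmia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Beat-by-beat cardiac arrhythmia classification for single-lead
    wearable ECG with a layered hidden Markov model. Provides digital signal
    conditioning (a second-order IIR powerline notch filter and a zero-order
    Savitzky-Golay smoother), a six-state ECG segmentation HMM with
    minimum-state-duration Viterbi decoding, a heuristic tri-axial
    accelerometer activity classifier used to gate motion-corrupted beats, a
    four-state ergodic beat-classification HMM (Normal, PVC, APC, Invalid),
    beat-by-beat evaluation metrics (accuracy, sensitivity, positive
    predictivity and their beat-weighted averages), a fully annotated
    synthetic ECG plus accelerometer generator, and readers and writers for
    WFDB, CSV and JSON interchange formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
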
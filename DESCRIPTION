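Package: grfcast
Title: Predicting Normal Ground Reaction Force Waveforms from Sacral
    Accelerometry During Slope Running
Version: 0.1.0
Authors@R: person("grfcast", "developers", role = c("aut", "cre"),
    email = "grfcast@example.org")
Description: Predicts continuous normal (surface-perpendicular) ground
    reaction force (GRF) waveforms during uphill, level, and downhill
    running from biaxial sacral accelerometer data using a bidirectional
    long short-term memory (LSTM) network with a per-frame multilayer
    perceptron head. Includes the full signal-processing pipeline
    (downsampling, zero-phase Butterworth filtering, bodyweight
    normalization, sliding-window feature engineering), stance-phase
    segmentation with discrete kinetic variables (active peak, impulse,
    loading rate, contact time, step frequency), leave-one-subject-out
    cross-validation, slope-split validation, permutation feature
    importance, and a physically consistent synthetic gait simulator so
    the entire pipeline can be exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
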
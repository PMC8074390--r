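Package: semgintent
Title: Online-Adaptive Prediction of Lower-Limb Motion Intention from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts future knee joint angle and time to the next heel strike
    from synchronized surface electromyography (sEMG), inertial, and footswitch
    recordings during walking. Raw sEMG windows are compressed by a
    convolutional autoencoder whose channel layout is informed by muscle
    synergies estimated with non-negative matrix factorization; a multi-layer
    LSTM network maps the compressed feature together with a short motion
    history to the prediction target. A meta-learned coordinatewise LSTM
    optimizer counteracts sEMG distribution shift (fatigue, inter-subject
    variability) by online-tuning a small, fixed subset of network parameters.
    Includes a synthetic gait-recording generator with controllable
    distribution-shift knobs so that the full pipeline can be exercised and
    validated without access to human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
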
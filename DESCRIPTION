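Package: sitstand
Title: Posture Classification and Sedentary Bout Patterns from Hip-Worn
    Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating sitting versus
    non-sitting posture, sit-to-stand transitions and sedentary bout
    pattern variables from raw hip-worn triaxial accelerometer data in
    children. Reads ActiGraph raw (30 Hz) and 60-s counts CSV exports and
    activPAL events files; detects non-wear from counts with the Choi
    algorithm; classifies 10-s epochs as sitting or non-sitting with a
    convolutional + bidirectional LSTM sequence model trained by
    backpropagation; derives posture-based sedentary bout variables
    (total sedentary time, breaks, time in long bouts, mean and usual
    bout duration, power-law alpha); and evaluates agreement against
    thigh-inclinometer ground truth with confusion metrics, lag-tolerant
    transition pairing, and participant-level agreement statistics
    (bias, MAE, MAPE, Spearman, Lin's concordance). A synthetic-data
    generator produces paired ground-truth posture events, inclinometer
    registrations, raw acceleration and counts for simulated
    child-weeks, so the whole pipeline is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
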
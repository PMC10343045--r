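Package: multisync
Title: Time-Locking and Synchronisation Analysis for Multimodal Physiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and exploiting event time-locking between a
    high-rate electrophysiological research recorder and a hospital vital-signs
    monitor. Provides a software model of a trigger-to-annotation event bridge
    with configurable clock and marking-latency models, a dual-device session
    simulator with full ground truth (ECG, impedance pneumography, EEG,
    photoplethysmography and 1 Hz numerics), marking-precision estimation from
    push-button artifacts, inter-device lag estimation by bounded
    cross-correlation of ECG epochs, stimulus-locked epoching with baseline
    correction, Woody alignment and template projection for evoked responses,
    and adaptive-threshold breath detection with windowed respiratory-rate
    computation including an edge-gap padding rule for breathing pauses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
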
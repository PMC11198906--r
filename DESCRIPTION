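Package: duobeta
Title: Separation and Behavioral Correlates of Low and High Motor Cortical Beta Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating and characterizing two concurrent motor
    cortical beta rhythms (a low band near 16 Hz and a high band near 26 Hz)
    in local field potential recordings, and for relating their single-trial
    amplitudes to instructed and uninstructed behavior. Includes a session
    data model with trial cutting and resampling; spectral analysis with a
    two-minima aperiodic (1/f) estimator and a beta band dominance index;
    band-limited Hilbert envelope extraction and pooling by band dominance;
    hand kinematics with movement onset detection; offline gaze calibration,
    recursive saccade detection and blink detection; time-resolved linear
    model selection by BIC, shuffle-corrected joint peri-stimulus
    cross-correlograms, gaze-lag scans and spike-field phase locking with
    trial-shuffle nulls; random-forest condition decoding with shuffle chance
    bounds; and a synthetic session generator that plants all of the above
    structure with a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    arrow,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
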
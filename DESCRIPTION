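Package: sleepcouple
Title: Sleep-State Staging, Spectral Connectivity and Ripple-Spindle
    Coupling Analysis for Rodent Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multichannel rodent sleep recordings
    (cortical screw EEG, depth LFP, EMG): rule-based sleep staging into
    NREM/REM/waking-immobility/movement from 2-s bins, Welch power
    spectral density with 1/f whitening, interregional magnitude-squared
    coherence in canonical frequency bands, theta-gamma phase-amplitude
    coupling via the Kullback-Leibler modulation index, hippocampal
    sharp-wave-ripple detection with amplitude and duration criteria, and
    ripple-triggered cortical spindle-band power with inter-ripple
    normalization.  Includes group statistics (two-sample t-tests,
    permutation tests, Benjamini-Hochberg FDR), a synthetic multichannel
    LFP/EEG/EMG generator with exact ground truth for validation, and a
    config-driven pipeline over a cohort of animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
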
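Package: somnispike
Title: Spike-and-Wave Discharge Detection and Sleep Architecture Analysis for Rodent EEG/EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for spontaneous spike-and-wave discharges
    (SWDs) in 24-h mouse sleep EEG/EMG recordings: acquisition-chain
    filtering, rule-based vigilance-state scoring (WAKE/SWS/REM) in 10-s
    epochs, amplitude-and-cycle-criterion SWD detection with Welch spectral
    characterization of each event, sleep-architecture and fragmentation
    metrics, state attribution of discharges, conditional state-transition
    probabilities around SWD-containing epochs, and circadian statistics
    (hourly Zeitgeber-time histograms, Rayleigh uniformity test, 24-h
    cosinor fit). Includes a calibrated synthetic EEG/EMG generator with
    ground-truth hypnograms and event tables so every analysis stage can be
    validated against known truth, plus readers and writers for EDF
    signals, CSV hypnograms, and CSV event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
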
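Package: phaselock
Title: Generalized Phase Resetting and Phase-Locked Mode Prediction in
    Pulse-Coupled Neural Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring phase response curves (PRCs) of
    conductance-based Morris-Lecar neural oscillators in an open-loop
    protocol, composing single-stimulus PRCs recursively to obtain the
    resetting produced by multiple inputs per cycle, and predicting the
    existence and linear stability of phase-locked firing modes in a
    three-neuron master-slave network with a dynamic inhibitory feedback
    loop. Predictions are validated against direct closed-loop simulation
    of the fully coupled network. Includes bias-current calibration to
    target intrinsic periods, least-squares fitting of type-1 (SNIC)
    normal-form PRCs, the affine conductance-to-coupling calibration,
    spike-time return-map stability analysis, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
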
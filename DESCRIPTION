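Package: calosc
Title: Calcium Oscillation Screening for Neuronal Activity and Seizure Liability
Version: 0.1.0
Authors@R:
    person("calosc", "maintainers", email = "calosc@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-reader recordings of synchronized
    neuronal calcium oscillations in hiPSC-derived neuron/astrocyte
    co-cultures. Detects oscillation pulses from whole-well fluorescence
    traces (smoothing, differentiation, threshold detection of bottom/top
    peak pairs, background estimation), extracts the five standard waveform
    parameters (peak number, width, amplitude, area under the curve,
    peak-to-peak time), computes per-well percent change from baseline,
    compares treatments to same-plate vehicle wells with rank-sum tests and
    nonparametric tolerance intervals, and classifies drugs for neuronal
    activity and potential seizure risk (sensitivity, specificity, PPV, NPV,
    predictivity). Includes a synthetic plate simulator with ground-truth
    pulse events and a packaged 25-drug reference panel for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
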
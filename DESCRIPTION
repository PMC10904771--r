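Package: axoflux
Title: Analysis of Toxin-Modified Action-Potential Generation in the Axon
    Initial Segment from Fluorescence and Electrode Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how slowing of voltage-gated sodium-channel
    inactivation (e.g. by scorpion alpha-toxins) reshapes action-potential
    generation in the axon initial segment. Implements the half-inactivation
    time (T50) statistic for voltage-clamp sodium currents with Hill-type
    dose-response normalisation; a preprocessing chain for high-speed
    fluorescence recordings (ROI extraction, trial averaging,
    multi-exponential photobleaching correction, dF/F0, optical membrane
    potential normalisation, bridge and junction-potential correction);
    logistic model-function fitting of sodium and calcium indicator
    transients (multi-sigmoid sum and 4-sigmoid product) with ionic-current
    estimation as the analytic time-derivative of the fits; action-potential
    amplitude/width metrics, percent-change and paired statistics; and a
    seeded biophysical simulator (Hodgkin-Huxley-style soma plus axon
    cable, toxin-slowed inactivation, sodium-channel calcium permeability,
    fluorescence forward model) that generates synthetic cohorts with the
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
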
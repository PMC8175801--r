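Package: stancekit
Title: Intermittent Postural Control Modeling and Perturbed-Stance
    Posturography with EEG Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates human upright stance as a double inverted pendulum
    stabilized by a delayed, intermittently switched
    proportional-derivative controller with a transient reflexive
    controller, and provides the analysis chain used to study perturbed
    stance: phase-plane and stable-manifold analytics, center-of-pressure
    and center-of-mass posturography (sway metrics, spectral scaling
    exponents, event-locked averaging, EMG envelopes, inverse dynamics),
    and EEG time-frequency analysis (event-related potentials,
    Morlet-wavelet event-related spectral perturbation with bootstrap
    significance masking, inter-trial coherence, band summaries).
    Ground-truth-labeled synthetic trials and EEG epochs allow every
    analysis stage to be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
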
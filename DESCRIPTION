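Package: fefattn
Title: Attention and Glutamatergic Drug Modulation Analysis for Frontal Eye
    Field Spike Trains
Version: 0.1.0
Authors@R:
    person("Martin", "Keller", email = "m.keller@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how iontophoretic blockade of ionotropic
    glutamate receptors changes excitability and attentional signals in
    frontal eye field (FEF) neurons. Provides a synthetic-session generator
    emulating a covert spatial-attention dimming task (gain-modulated
    Poisson spiking with trial-wise gamma gain, bimodal spike waveforms,
    fixational eye traces), epoch-rate extraction and trial filtering,
    waveform-based narrow/broad classification with a Monte-Carlo
    calibrated Hartigan dip test, k-means cell-type clustering with
    AIC/BIC model selection, attention metrics (AUROC, drug modulation
    index, Cohen's D-prime, three-factor ANOVA gating), negative-binomial
    gain-variance estimation, behavioural analyses (signal-detection
    d-prime, reaction-time normalisation, chi-square error tests,
    velocity-threshold microsaccade detection), and a two-stage spiking
    attractor network with graded NMDA-conductance blockade.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
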
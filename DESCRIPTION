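Package: columnet
Title: Conductance-Based Cortical Column Networks with Long-Range Disynaptic Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates attractor networks of Hodgkin-Huxley point neurons
    (pyramidal, basket, Martinotti and VIP cells) arranged in a
    hypercolumn/minicolumn cortical topology. Synapses use kinetic AMPA,
    NMDA and GABA-A receptor models with Tsodyks-Markram short-term
    plasticity, and peak conductances are calibrated against unitary
    PSP amplitudes. Long-range excitation onto Martinotti cells produces
    surround suppression and center saliency; a VIP-mediated disinhibitory
    pathway abolishes it. Includes network construction with variant
    wirings, Ornstein-Uhlenbeck point-conductance background noise and
    feedforward drive, a compiled fixed-step integrator with delayed spike
    delivery, population rate analysis, and pre-registered experiment
    runners at reduced desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
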
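Package: placefieldinfo
Title: Spatial Information Transfer in Hippocampal Place-Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how trial-to-trial variability,
    place-field asymmetry and biophysical heterogeneity shape spatial
    information transfer within a single hippocampal place field. Generates
    theta-modulated presynaptic place-field drive (Gaussian or reflected
    Erlang envelopes) with additive, multiplicative or pink noise, samples
    presynaptic spike trains, feeds them through GHK-based AMPAR/NMDAR
    synapses into a single-compartment resonant spiking surrogate, and
    analyses the resulting firing-rate profiles with location-wise mutual
    information and stimulus-specific information (with Treves-Panzeri bias
    correction). Includes stochastic parameter-population sampling with
    electrophysiological validation, noise sweeps, virtual ion-channel
    knockouts, correlation and PCA reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
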
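Package: kinmass
Title: Thalamocortical Neural Mass Model with Kinetic Synapse Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-population (thalamocortical relay and thalamic
    reticular nucleus) neural mass model in which synaptic transmission is
    represented by kinetic receptor dynamics - two-state ligand-gated AMPA
    and GABA-A channels and a G-protein secondary-messenger cascade for
    GABA-B - instead of the conventional alpha-function kernel. Provides a
    seeded stochastic retinal drive, an adaptive Runge-Kutta-Fehlberg
    integrator with a fixed-step oracle, an ensemble-averaging protocol,
    an EEG-band spectral analysis chain (decimation, zero-phase Butterworth
    band-pass, short-time Fourier transform, band power), a dynamical-regime
    classifier (quiescent, point attractor, limit cycle, spindling, slow
    oscillation), and one-dimensional parameter sweeps with bifurcation
    detection and receptor-blockade experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
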
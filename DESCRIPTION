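Package: stellate
Title: Simulation and Bifurcation Analysis of an Entorhinal Cortex
    Stellate-Cell Neuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based single-compartment model of layer II medial
    entorhinal cortex stellate cells with a spike-triggered
    after-hyperpolarisation (AHP) current.  Provides deterministic and
    stochastic (Heun scheme) integration of the membrane equations, the
    clustered-firing statistic P_C, equilibrium continuation with
    saddle-node and Hopf detection, Poincare return-map analysis of
    periodic orbits (Picard iteration, map Jacobians, Floquet multipliers,
    map Lyapunov exponents, flip and homoclinic localisation), fast-slow
    decomposition and burster classification, and multitaper (DPSS)
    spectral analysis of subthreshold membrane-potential fluctuations.
    Channel kinetics are read from an editable definition file.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
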
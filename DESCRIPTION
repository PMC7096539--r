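Package: epidyn
Title: Simulation and Bifurcation Analysis of the Epileptor Neural Mass Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing the Epileptor, a five-variable
    phenomenological neural mass model of seizure dynamics. Provides the full
    model and its fast/slow subsystems with analytic Jacobians, deterministic
    (fixed-step Runge-Kutta) and stochastic (Euler-Maruyama) integrators,
    equilibrium location with closed-form branch solutions and trace/determinant
    stability classification, grid continuation of (z, x1) bifurcation diagrams
    with saddle-node, Hopf, homoclinic and SNIC detection, Pontryagin averaging
    for locating slow-fast periodic orbits and saddle-node-of-periodic-orbit
    bifurcations, and per-point classification of model behaviour (seizure-like
    events, refractory-status-epilepticus-like limit cycles, depolarization
    block, normal state) over the (m, x0) parameter plane.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
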
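Package: cdc42sim
Title: Bulk-Surface Turing Analysis and Simulation of Cdc42-Driven Cell
    Polarisation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a dimensionless bulk-surface reaction-diffusion model
    of Cdc42-mediated cell polarisation. Provides the membrane kinetics and
    the nonlocal cytosolic mass-conservation coupling, steady-state analysis
    of the spatially homogeneous system (polynomial root finding with Newton
    refinement, trapping-region and necessary-condition checks), linear
    stability analysis over the spherical-harmonic spectrum with
    classification into classic and non-classic diffusion-driven (Turing)
    instability, parameter-plane mapping, an implicit-explicit finite-element
    simulator of the reduced two-state system on a triangulated unit sphere,
    pole recognition with quantitative polarisation measures, multi-seed
    parameter sweeps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
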
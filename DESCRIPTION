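Package: retistim
Title: Patient-Parametric Simulation of Epiretinal Prosthesis Stimulation
Version: 0.1.0
Authors@R:
    person("retistim", "maintainers", email = "maintainers@retistim.dev",
           role = c("aut", "cre"))
Description: A self-contained simulator of epiretinal electrical stimulation
    of retinal ganglion cells (RGCs). Generates parametric patient geometry
    (eye dimensions, microelectrode array pose, retinal thickness field,
    fibrotic capsule), solves the quasi-static bioelectric field around an
    active electrode with a finite-volume Poisson solver on a conductivity
    grid, drives multi-compartment five-channel Hodgkin-Huxley-type RGC cable
    models placed by Lloyd centroidal-Voronoi sampling with axons routed
    along Jansonius nerve-fiber trajectories, predicts per-electrode
    activation thresholds by bisection, and includes a simulated
    psychophysics harness (adaptive Weibull maximum-likelihood threshold
    estimation with catch-trial auditing) plus model-versus-observed
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
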
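Package: neuropilsim
Title: Monte Carlo Simulation of Glutamate Spillover and Astroglial
    Uptake in Stochastic Neuropil Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Particle-based Monte Carlo simulator of glutamate release,
    diffusion, and astroglial transporter binding in a stochastically
    generated neuropil represented as randomly scattered, overlapping
    spheres of distributed size. Generates geometries calibrated to a
    target extracellular volume fraction (alpha) and astroglial tissue
    share, releases Brownian particles into a central synaptic cleft,
    reflects them specularly off cell surfaces, and captures them near
    astroglial membranes with an exponential-lifetime hazard governed by
    a binding time constant (Psi). Includes analysis of radial free and
    bound concentration profiles, free/bound ratios, spatial length
    constants (lambda), multi-trial averaging, and Psi-by-alpha parameter
    sweeps, plus a command-line interface and CSV/JSON serialization.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
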
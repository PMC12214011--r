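Package: turimm
Title: Turing-Pattern Resilience in a Spatial Tumour-Immune Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of a three-species reaction-diffusion model of solid
    tumour immunotherapy (effector cells, tumour cells, IL-2), in which
    subcritical Turing instabilities create spatially patterned tumour states
    that persist far into treatment regimes where the well-mixed model
    predicts clearance. Provides the model kinetics and nondimensionalisation,
    homogeneous steady-state and Turing-instability classification over
    treatment parameters, pseudo-arclength continuation of homogeneous and
    patterned 1D steady states with fold and Hopf detection, and stiff
    method-of-lines simulation in 1D and 2D (square and disc) geometries with
    time-dependent and boundary-driven treatment protocols.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
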
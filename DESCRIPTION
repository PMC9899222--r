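Package: radonroom
Title: Indoor Radon Transport, Ventilation and Dose Modelling for a Single Room
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale finite-volume simulation of steady airflow and
    radon-222 transport in a single naturally ventilated room, under open-
    and closed-door scenarios. Provides a structured-grid SIMPLE solver for
    incompressible flow with selectable turbulence closure (constant
    effective viscosity or standard k-epsilon with wall functions), a
    positivity-preserving advection-diffusion-decay solver for the radon
    activity concentration, the analytical well-mixed (box) ventilation
    model with generation-rate calibration, annual-effective-dose
    assessment, detector-comparison statistics, and synthetic data
    generators (manufactured solutions and noisy detector readings) for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
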
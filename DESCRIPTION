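Package: puncturesim
Title: Finite-Element Simulation of Flat-Probe Puncture Tests on Layered Fruit Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale finite-element modelling of the puncture (Magness-Taylor
    style) firmness test on layered fruit tissue such as papaya. Provides a
    bilinear elastoplastic (J2, linear isotropic hardening) material model with
    parameter extraction from stress-strain records, moisture-based Poisson's
    ratio and density formulas, a graded axisymmetric quadrilateral mesher for
    a skin-over-flesh sample, implicit quasi-static and explicit dynamic
    solvers with frictionless rigid flat-punch penalty contact and
    plastic-strain element erosion, bioyield-point extraction from
    force-deformation curves, seeded synthetic-data generators emulating
    puncture records sampled at 200 points per second, parameter sensitivity
    studies, inverse-analysis calibration, and a validation pipeline comparing
    simulated bioyield forces against measured storage-day by probe-velocity
    tables via the relative-error statistic.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
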
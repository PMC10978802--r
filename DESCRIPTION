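Package: nemaindent
Title: Three-Compartment Finite-Element Model of C. elegans Indentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atomic-force-microscopy indentation of Caenorhabditis
    elegans with a nonlinear three-compartment (cuticle+hypodermis, muscle,
    pseudocoelom) finite-element model of the nematode body. Provides a
    structured hexahedral mesher for the layered-cylinder idealization, a
    nearly incompressible neo-Hookean total-Lagrangian solver with frictionless
    penalty contact against a rigid spherical indenter, AFM force-curve
    processing (baseline zeroing, contact-point detection, cantilever-bending
    correction, Hertz/Sneddon fitting, bulk-stiffness regression), inverse
    calibration of per-compartment Young's moduli against measured or synthetic
    force-displacement curves, and a synthetic raw-curve generator for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
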
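Package: aortapulse
Title: Reduced-Order Pulse-Wave Hemodynamics of the Aging Human Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds an idealized, branched model of the human aortic tree,
    ages it virtually by prescribing population-averaged changes in caliber,
    regional length, tortuosity, wall thickness and biaxial material
    stiffness, and simulates one-dimensional blood flow through it with
    three-element Windkessel outlets and viscoelastic external tissue
    support. Computes clinical metrics of arterial stiffening (pulse
    pressure, distensibility, foot-to-foot pulse wave velocity via the
    intersecting-tangent algorithm, and cyclic stored strain energy) and
    their spatial and temporal correlations with prescribed circumferential
    stiffness, together with the calibration loops that tune distal
    Windkessel resistances to target mean arterial pressure and external
    support stiffness to target aorto-iliac pulse wave velocity. Includes a
    four-fiber-family constitutive model with small-on-large linearization
    about the in vivo state for users supplying their own wall parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
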
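Package: oxywindow
Title: Oxygen Transport Modelling over Microfluidic Gas-Exchange Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional reaction-diffusion modelling of oxygen partial
    pressure in skeletal-muscle tissue overlying a gas-permeable PDMS membrane
    with patterned gas-exchange windows. Implements a two-region (tissue/PDMS)
    finite-difference model with Michaelis-Menten oxygen consumption and a
    homogeneous capillary source, advanced in time by a semi-implicit
    (implicit-explicit) scheme; gas-challenge protocols as piecewise-constant
    window boundary conditions; gradient-threshold metrics for the penetration
    depth, lateral spread and settling time of an oxygen perturbation; and
    closed-form and dense-Newton verification oracles for the solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
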
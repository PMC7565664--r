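Package: scadsorb
Title: Continuum Modelling and Calibration of Supercritical Drug Adsorption
    into Aerogel Monoliths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and parameter estimation for supercritical
    adsorption (impregnation) of an active pharmaceutical ingredient from
    supercritical carbon dioxide into a porous silica-aerogel monolith held
    in a batch high-pressure reactor.  Provides a thermophysical property
    layer (Peng-Robinson equation of state for CO2 density, the He-Yu
    correlation for molecular diffusivity, solubility table interpolation),
    Langmuir-type adsorption kinetics with a kinetic-theory rate constant,
    an axisymmetric finite-volume reaction-diffusion solver for the coupled
    free-volume/porous-body species balances, golden-section calibration of
    the effective diffusivity and maximum-loading correlations from loading
    kinetics curves, and a seedable synthetic kinetics generator for
    closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
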
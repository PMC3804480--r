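Package: ktap
Title: Thermostatted Hybrid Kinetic Models of Interacting Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and moment-analysis toolkit for hybrid kinetic models of
    multicellular systems in which cell velocity takes finitely many discrete
    values while a continuous activity variable evolves through binary
    conservative (activity-redistributing) and nonconservative
    (proliferative/destructive) interactions, optionally driven by an external
    field damped by a Gaussian-type thermostat. Provides finite-volume upwind
    time integration of the kinetic integro-differential system, moment
    functionals of the discrete-velocity distribution, the Riccati ordinary
    differential equation layer governing the controlled first activation
    moment (numerical and constant-coefficient closed-form solution paths), and
    a cross-validation harness comparing moments measured on the kinetic
    solution against the moment ODEs, with blow-up detection for mass-growing
    regimes and reproducible YAML-configured command line runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
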
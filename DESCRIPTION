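Package: torquepuck
Title: Torque-Dipole Hydrodynamics of Bacteria-Driven Microdiscs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and inference for the rotation of symmetric microdiscs
    ("pucks") driven by the flagellar torque dipole of confined swimming
    bacteria. Provides a regularized-Stokeslet boundary-element solver for
    Stokes flow driven by point torques (rotlets) inside a no-slip square
    microchannel, wall-traction and transmitted-torque evaluation including
    the dimensionless torque-transmission constant, the analytic angular
    dynamics of a puck during single-bacterium channel crossings and in
    closed chambers with multiple occupants, a minimal collision-rectification
    model for plain discs in a chiral bacterial bath, synthetic trajectory
    generators emulating the experimental observables, and estimators for
    rotation rates, rotational diffusivity (mean squared angular
    displacement), Stokes-Einstein mobility and the dipole-length ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
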
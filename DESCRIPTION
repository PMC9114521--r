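Package: depmech
Title: Dielectrophoretic Single-Cell Stretching: Electromechanics, Device
    Models, and Strain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis for automated dielectrophoresis (DEP) based
    measurement of single-cell mechanical properties in a microfluidic
    trap-array device. Provides the DEP electromechanical core (complex
    permittivity, Clausius-Mossotti factor, crossover frequency, DEP force,
    stretching stress, and Young's modulus), a two-dimensional finite-difference
    Laplace solver for electrode geometries and the dimensionless geometric
    constant of the stress model, a lumped hydraulic-resistance network of the
    capture-port array, a seeded synthetic device and controller simulator
    (stochastic per-port capture, saturating stretch traces at video frame
    rate, capture-stretch-release state machine), and strain/modulus population
    analysis with group comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
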
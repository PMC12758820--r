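Package: odorcal
Title: Mass-Transfer Calibration of Odor Delivery Devices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts and calibrates the absolute odorant concentration
    delivered by vial-based odor delivery devices used in insect
    electrophysiology. Implements a two-film mass-transfer model of an
    odor source (liquid and headspace) coupled to a transport tube as a
    compartmental ODE system, closed-form pseudo-stationary
    concentrations from air-solvent partition coefficients,
    Sherwood-correlation predictions of the headspace transfer
    coefficient, nonlinear calibration of transfer coefficients from
    plateau measurements, partition-coefficient estimation from
    headspace GC-FID data (phase ratio variation and liquid
    calibration), source-lifetime computation, design-space sweeps over
    source diameter and airflow, and seeded synthetic-data generators
    for every measurement type the package consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    sandwich,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
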
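Package: cellbiophys
Title: Quantitative Cell Biophysics: Permeability Kinetics, Laurdan GP
    Imaging, and AFM Force-Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the quantitative biophysical
    characterization of cultured cells. Estimates osmotic water and
    glycerol permeability coefficients from relative cell-volume time
    courses via a two-compartment osmotic model, and hydrogen-peroxide
    influx rate constants from dye-oxidation kinetics. Computes calibrated
    Laurdan generalized polarization (GP) images with automated
    plasma-membrane ROI extraction. Analyzes AFM force-distance curves for
    Hertzian elasticity (Young's modulus, tip penetration depth,
    Gaussian-fitted population peaks), single-cell adhesion (detachment
    force, work of detachment, jump and membrane-tether event
    classification), and topographic morphometry (area, volume,
    elongation, roughness). Includes wound-closure migration and
    efficiency-corrected qPCR knockdown quantification, and a seeded
    synthetic-data generator that produces every input with known ground
    truth under condition presets for silencing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
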
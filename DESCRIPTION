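Package: ferrobead
Title: Magnetic Positioning of Ferrogel Beads in Tube Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Models the remote magnetic positioning of millimetre-scale
    calcium-alginate ferrogel beads in a fluid-filled tube. Provides gel and
    filler composition arithmetic (swelling ratios, magnetite weight and
    volume fractions, susceptibility from a reference-composite calibration),
    an electromagnet field model with a demagnetization-corrected attraction
    force and dipole-dipole array corrections, parametric hysteresis loops
    with parameter extraction, reduced-order hydrodynamic closures (laminar
    tube profile, Schiller-Naumann drag with near-wall correction,
    shear-induced lift), a force-balance trajectory simulator with
    capture/detachment classification, and synthetic-data generators for
    particle-size distributions, bead populations and noisy video tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
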
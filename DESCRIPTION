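Package: rtmscoil
Title: Design and Field Simulation of Miniaturized rTMS Coils for Rodents
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for designing and validating miniaturized
    repetitive transcranial magnetic stimulation (rTMS) coils for murine
    studies. Provides closed-form flat-spiral design estimates (Wheeler
    inductance, coil-centre flux density), a Biot-Savart magnetostatic
    solver for circular and figure-of-eight windings based on complete
    elliptic integrals, focality metrics on observation planes, a Neumann
    partial-inductance cross-check, quasi-static induced electric fields
    in a layered murine head phantom, a lumped Joule-heating estimate,
    a synthetic Tesla-meter measurement generator, and the one-way ANOVA
    comparison stage used to validate simulation against measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
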
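Package: proboscipeda
Title: Demographic Inference from Fossil Elephant Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the body size, age and population age
    structure of proboscidean trackmakers from footprint measurements.
    Implements the sex-specific linear regressions of shoulder height on
    foot length and the species power law relating body mass to shoulder
    height, inverts Von Bertalanffy growth curves to obtain (possibly
    censored) age estimates, screens track tables for slippage and
    overstepping, assigns individuals to age classes and tabulates the
    demographic frequency of a track assemblage. A seeded forward
    simulator of herd trackways closes the loop for parameter-recovery
    validation, and the measured track table of the Matalascanas Trampled
    Surface is packaged as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
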
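Package: fovearrest
Title: Quantifying Arrested Foveal Development from Retinal Layer Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Morphometric analysis of arrested foveal development in adults
    born preterm, from OCT-derived retinal layer thickness profiles.
    Estimates retardation of centrifugal layer displacement as the
    horizontal shift between cumulative layer-thickness curves of preterm
    and control groups, computes the foveal developmental arrest (FDA)
    index, extracts outer plexiform layer thickness from A-scan
    reflectivity profiles by the half-height criterion, and models the
    structural consequences of retarded displacement as losses in areal
    and volume magnification, including cone-pedicle minification and
    sphere-equivalent diameters. A seeded synthetic-cohort generator with
    analytically known displacement ground truth supports validation
    without access to raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
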
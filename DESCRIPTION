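Package: hspcompat
Title: Group-Contribution Hansen Solubility Parameters and Polymer-Drug
    Compatibility Screening for Micelle Formulations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates Hansen solubility parameters (dispersion, polar and
    hydrogen-bonding components) from functional-group contributions
    (Hoftyzer-van Krevelen constants, Fedors molar volumes), screens
    drug-polymer compatibility through the Hildebrand-Scatchard
    Flory-Huggins interaction parameter, and analyses polymer micelle
    formulation data (loading capacity and efficiency, stability time
    courses, redispersion recovery, dose conversions). Ships a seeded
    synthetic solubilization-data generator so the full
    prediction-versus-experiment ranking pipeline can be exercised and
    validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
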
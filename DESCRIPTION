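Package: stomres
Title: Residual Leaf Conductance and Ball-Berry Stomatal Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates residual (cuticular plus incomplete-closure) leaf
    conductance from detached-leaf drying curves and from gas-exchange
    records, fits and compares Ball-Berry-family stomatal conductance
    models that treat residual conductance either as a fitted intercept,
    a measured intercept, or a measured minimum-conductance floor, and
    couples the fitted models to Farquhar-von Caemmerer-Berry
    photosynthesis to simulate intercellular CO2 and leaf transpiration
    across light and temperature gradients. Includes a synthetic
    gas-exchange, drying-curve and A/Ci data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
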
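Package: rlrpaco2
Title: Non-Invasive PaCO2 Estimation from End-Tidal CO2 and Ventilation Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating non-invasive estimators of the
    arterial partial pressure of carbon dioxide (PaCO2) in mechanically
    ventilated neonates from end-tidal CO2 (etCO2) and routinely recorded
    ventilator and vital-sign channels. Provides a seeded synthetic generator
    for ovine-style ventilation trials with intermittent blood-gas analyses,
    capnogram synthesis and end-tidal extraction, centred and trailing window
    averaging with the study exclusion filters, a candidate-feature catalogue
    (identity, square, cube, conditional logarithm, oxygenation indices),
    Huber M-estimator regression via iteratively reweighted least squares with
    iterative residual-correlation variable selection, a frozen published
    estimation equation together with an online estimation loop, withholding
    rules and two comparator baselines, and agreement evaluation (MAE, SD, SE,
    quantile-based Bland-Altman limits of agreement, method comparison tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
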
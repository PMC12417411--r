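Package: co2resp
Title: CO2-Response Curve Fitting and Respiratory Flux Partitioning for
    Leaf Gas Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits biochemical (Farquhar-type) and empirical (rectangular
    hyperbola, Michaelis-Menten, modified rectangular hyperbola)
    CO2-response models to A/Ca and A/Ci leaf gas-exchange curves measured
    at ambient (21%) and low (2%) oxygen, partitions respiration in the
    light into photorespiratory and mitochondrial components by the
    differential-oxygen method, computes CO2 recovery and inhibition
    profiles of photorespiration, and quantifies the ambient-CO2 dependence
    of all respiratory fluxes by polynomial and linear regression.  Includes
    a synthetic gas-exchange generator reproducing the measurement design
    (12 CO2 levels, two O2 levels, light and dark, replicated) so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
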
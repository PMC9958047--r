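Package: thermolegacy
Title: Thermal Phenotypes of Marine Microbial Enzymes and Habitat Thermal Legacy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies enzyme thermal phenotypes and relates them to the
    thermal legacy of the habitat. Converts microplate absorbance kinetics
    into specific activities and temperature optima (Topt), fits
    five-parameter sigmoids to circular-dichroism melting curves to obtain
    denaturation temperatures (Td), and performs constraint-network rigidity
    analysis (body-bar pebble game, thermal constraint dilution, cluster
    configuration entropy) to compute phase transition temperatures (Tp).
    A statistical layer provides AIC model ladders over environmental
    covariates, segmented (breakpoint) regression, variance-homogeneity
    tests, thermal-variability summaries, growth-rate extraction and one-way
    ANOVA. A synthetic-data generator with controllable ground truth makes
    the whole pipeline testable without any external measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
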
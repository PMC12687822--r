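Package: habnet
Title: Mosquito Habitability Modelling from Daily Climate Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end species distribution modelling toolkit for
    vector mosquitoes driven by daily gridded climate data. Derives five
    daily climate covariates (temperature range, mean temperature,
    relative humidity via the August-Roche-Magnus equation, total
    precipitation, wind speed), builds presence/pseudo-absence training
    sets with cosine-latitude background sampling, trains a flattened-
    sequence feedforward neural network with Adam and AUC-based early
    stopping, calibrates raw scores to false negative rates ("risk
    percentiles") through the empirical CDF of presence scores, and
    provides covariate ablation, circular season-diameter/seasonality
    analytics, historical-change maps, and population-days-at-risk burden
    estimation. Includes a fully synthetic world generator with a known
    habitability law so the whole pipeline is testable offline.
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
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
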
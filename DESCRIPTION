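Package: bloomcast
Title: Process-Based Spring Phenology Modelling for Temperate Fruit Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples Dynamic Model chill accumulation with Growing Degree
    Hours heat accumulation into a process-based predictor of full-bloom
    dates for temperate fruit trees, with three calibration schemes
    (default submodels, fully cultivar-specific, and species-shared
    submodels with cultivar-specific chill and heat requirements), an
    intermediate-parameter reparameterization of the chill kinetics,
    weather cleaning and hourly interpolation, validation metrics
    (RMSE, RPIQ, bias), temperature-response diagnostics, and a
    synthetic weather and bloom-date generator for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    geosphere,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
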
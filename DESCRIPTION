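Package: taluscape
Title: Climate-Mediated Extirpation Analysis for Talus-Dwelling Metapopulations
Version: 0.1.0
Authors@R:
    person("Talus", "Maintainers", email = "maintainers@taluscape.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for reconstructing and projecting the
    climatic collapse of talus-dwelling small-mammal metapopulations such as
    the American pika (Ochotona princeps). Implements post-bomb radiocarbon
    calibration of fecal-pellet Fraction Modern values with highest-density
    95% calendar-age ranges, quality control, imputation and trend analysis
    of daily weather-station records, logistic occupancy modelling with
    refugial mean-summer-temperature predictors at multiple dispersal radii
    and AICc model selection, and raster projection of climatically suitable
    habitat area under uniform warming offsets. A synthetic-data module
    generates every input the pipeline consumes, so the full chain is
    testable offline.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
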
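Package: arocm
Title: Average Rate of Change in Methylation and Maximum Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the average rate of change in DNA methylation (AROCM)
    within species-tissue or breed strata and relates it to species maximum
    lifespan. Implements the decomposition of the rate into the
    methylation-age correlation and the standard deviation of relative age,
    the SD(R)-power adjustment with quartile-coefficient-of-dispersion based
    selection of the adjustment power, closed-form proposition checks linking
    adjusted rates to the inverse of lifespan, a piecewise log-linear
    life-course model relating aging rates in young and old animals, stratum
    quality-control filters, comparative cross-species analyses
    (species-level aggregation, lifespan correlations, lifespan-group trend
    tests, multivariate lifespan models), and a synthetic multi-stratum
    methylation study generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
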
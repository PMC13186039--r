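Package: soilcdrisk
Title: Soil Cadmium Bioaccessibility Modelling and Probabilistic Health Risk
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the intestinal-phase bioaccessible fraction
    of cadmium in soils and propagating it into probabilistic human-health
    risk estimates. Includes a synthetic-data generator that reproduces the
    statistical structure of compiled national soil/bioaccessibility surveys
    (property ranges, in-vitro method mixture, log-linear dependence of
    bioaccessible Cd on total Cd and sand fraction), nonparametric screening
    statistics, random-forest based imputation, Cook's-distance outlier
    filtering, stepwise and random-forest regression models with Shapley
    attribution, ordinary-kriging spatial interpolation with regional
    geometric-mean aggregation, and a Monte Carlo engine for hazard-quotient
    and carcinogenic-risk distributions with bioaccessibility adjustment and
    contribution-to-variance sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
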
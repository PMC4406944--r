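Package: sporefit
Title: Quantitative Genetics of Social Fitness Trade-Offs in Dictyostelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of strain-level trade-offs between spore
    number, spore size, spore viability and chimeric sporehead representation in
    the social amoeba Dictyostelium discoideum. Provides a synthetic strain
    generator with a configurable genetic covariance (G) matrix, a multi-trait
    Bayesian mixed model fitted by conjugate Gibbs sampling (inverse-Wishart
    prior on G) reporting broad-sense heritabilities and genetic correlations
    with credible intervals, a dominance-hierarchy module with the
    triangle-transitivity statistic and a randomization null, and a realized
    social fitness module (representation times viability) with linear and
    quadratic selection-surface fits. A seeded end-to-end pipeline writes all
    tables and reports as CSV/JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
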
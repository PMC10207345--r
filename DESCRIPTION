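Package: stgap
Title: Bayesian Spatiotemporal Modelling of Gender Gaps in Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent Gaussian spatiotemporal panel models for country-level gender
    gaps in life expectancy and related outcomes. Implements the BYM2 spatial
    random effect on a country adjacency graph, a random-walk temporal trend, an
    exchangeable space-time interaction, and log-covariate fixed effects with
    optional region-specific exposure coefficients, fitted by
    Metropolis-within-Gibbs MCMC over the sparse latent field. Includes
    population-weighted exposure aggregation from gridded pollutant and
    population arrays, DIC/WAIC model comparison, a descriptive trend/peak
    taxonomy for country trajectories, and synthetic-panel generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
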
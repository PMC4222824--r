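Package: gppval
Title: Validation of Process-Based and Light-Use-Efficiency GPP Models
    Against Eddy-Covariance Observations
Version: 0.1.0
Authors@R:
    person("Site-Flux", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A pipeline for validating daily gross primary production (GPP)
    models at eddy-covariance sites. Provides a Farquhar/Collatz big-leaf
    photosynthesis forward model for C3 and C4 vegetation, a light-use-
    efficiency GPP model driven by NDVI, PAR, temperature and the Bowen
    ratio, nighttime-NEE flux partitioning to tower "observed" GPP
    (Lloyd-Taylor respiration), Metropolis-Hastings MCMC inversion of the
    maximum carboxylation rate Vcmax with per-plant-functional-type pooling,
    validation statistics (R2, RMSE, relative predictive error) with
    biome-level aggregation and paired model comparison, and a seeded
    synthetic-site generator with known truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
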
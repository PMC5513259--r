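Package: efpcap
Title: Ecosystem Photosynthetic Capacity from Eddy-Covariance Light
    Response Curves and Its Links to Leaf Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ecosystem photosynthetic capacity, an ecosystem
    functional property, from half-hourly eddy-covariance gross primary
    productivity (GPP) and incoming radiation. Nonrectangular hyperbolic
    light response curves are fitted in 5-day moving windows against PAR
    or APAR; daily Amax, GPP at saturating light (GPPsat) and the
    cumulative light response integral (GPPcum) are extracted, screened
    by goodness of fit, summarised to annual values by percentile, and
    their interannual variability compared across estimators. Site-level
    community-weighted mean leaf traits (nitrogen, phosphorus, carbon,
    SLA, delta 13C) are aggregated from species tables and linked to the
    capacity estimates by regression, distance correlation,
    leave-one-out cross-validation, analysis of covariance,
    year-resampling tests and stepwise AIC selection over transformed
    trait predictors. A synthetic-data generator with known ground truth
    (radiation, fluxes, 16-day FAPAR with neighbour pixels, trait
    tables) makes the whole pipeline testable without restricted flux or
    trait databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
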
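Package: aviarytraits
Title: Consistent Individual Differences and Behavioural Syndromes from
    Aviary Zone-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying long-term animal personality in
    commercial laying hens from zone-transition tracking streams. Extracts
    five daily spatial behaviours (vertical travelled distance, winter
    garden presence, nestbox tier timing, sleeping tier, and a feed
    delivery response statistic) from occupancy intervals, estimates
    adjusted repeatability on the latent scale for Gaussian, binary and
    gamma responses with parametric-bootstrap confidence intervals, fits a
    Bayesian multivariate hen-random-intercept model for among-individual
    (syndrome) correlations, and summarises behavioural-profile axes via
    eigendecomposition of the among-individual correlation matrix. Includes
    a two-level synthetic flock simulator (behaviour-level with known
    variance components, and trajectory-level emitting transition streams)
    used to validate every stage against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    glmmTMB,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
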
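Package: stmobility
Title: Bayesian Spatiotemporal Modelling of Seasonal Subnational Mobility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seasonal subnational human mobility from
    differentially-private origin-destination flow releases. Implements the
    Laplace-noise-plus-suppression release mechanism for weekly flow counts,
    monthly mobility change ratios against a January baseline, county-level
    covariate construction with a collinearity screen, and a Markov chain
    Monte Carlo fit of a Gaussian spatiotemporal regression with BYM2 spatial,
    AR1 temporal and space-time interaction random effects, with posterior
    summaries, DIC and validation metrics. A synthetic-data generator emulates
    the statistical structure of aggregated mobility datasets so the whole
    pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
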
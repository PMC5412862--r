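Package: dasypop
Title: Dasymetric Population Mapping with Point-Event Density Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for random-forest dasymetric disaggregation of census counts
    to a population grid, with geolocated point-event densities (for example
    geotagged social-media posts) as an additional covariate layer. Provides a
    seeded synthetic study-region generator (spatially autocorrelated covariate
    fields, a nested two-level administrative hierarchy with consistent census
    counts, and biased point events), floor-rule point gridding, binary-class
    and Euclidean distance-to covariate construction, zonal summarization,
    ensemble fitting with out-of-bag permutation importance, count-preserving
    dasymetric redistribution, and cross-scale accuracy assessment
    (RMSE, percent RMSE, MAE, paired model comparison, average spatial
    resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
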
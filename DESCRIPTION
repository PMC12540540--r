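Package: agrizone
Title: Management-Zone Delineation for Site-Specific Nutrient Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geostatistical delineation of soil-fertility management zones
    for precision agriculture: simulation of spatially autocorrelated
    multi-property soil fields, empirical semivariogram estimation and
    weighted-least-squares model fitting (spherical, exponential, Gaussian),
    Cambardella spatial-dependence classification, ordinary kriging with
    leave-one-out cross-validation (nRMSE, R-squared), covariance-based
    principal component analysis with eigenvalue retention, fuzzy C-means
    clustering with fuzzy performance index and normalized classification
    entropy model selection, one-way ANOVA zone validation with compact
    letter displays, field-versus-zone variability-reduction accounting,
    and soil-test-based targeted-yield fertilizer recommendations with
    economic evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    multcomp,
    optparse
Config/testthat/edition: 3
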
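Package: endoexo
Title: Endo-Exogenous Growth-Rate Models for Bivoltine Butterfly Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling extinction risk of bivoltine butterfly
    populations from transect counts and monthly climate. Converts repeated
    flight-period transect counts into per-generation densities and growth
    rates (lambda), builds the 18 candidate predictors combining lagged
    densities with stage-windowed climate and topography (including the
    topographic solar radiation index, trasp), and fits endo-exogenous
    models per population and generation via genetic-algorithm subset
    selection by AIC followed by jack-knife partial least squares for
    coefficients, standard errors and p-values, with a random-forest
    robustness baseline and stratified-bootstrap balancing for pooled
    models. Includes a synthetic-data generator with known ground-truth
    coefficients so every pipeline stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
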
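Package: favourability
Title: Environmental Favourability Modelling for Species Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for presence/absence species distribution modelling with
    the prevalence-corrected environmental favourability function. Fits
    logistic generalized linear models on gridded environmental covariates,
    transforms predicted probabilities to favourability values that are
    comparable across datasets with different prevalence, performs forward
    stepwise predictor selection with order-of-inclusion bookkeeping,
    transfers fitted models between regions with extrapolation diagnostics,
    and evaluates discrimination with threshold-dependent indices
    (sensitivity, specificity, PCC, PPP, NPP, TSS, Kappa) and the area
    under the ROC curve. Includes a synthetic-landscape simulator with
    spatially autocorrelated covariates for benchmarking model
    transferability at the edge of a species' range.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
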
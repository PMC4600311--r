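Package: smrmap
Title: Bayesian Spatio-Temporal Disease Mapping of Standardized
    Mortality Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Small-area spatio-temporal analysis of mortality counts:
    indirect age standardization against national reference rates,
    hierarchical Poisson and negative binomial regression with intrinsic
    conditional autoregressive (ICAR) spatial random effects fitted by
    Metropolis-within-Gibbs MCMC, model comparison by the Deviance
    Information Criterion, and export of smoothed standardized mortality
    ratio (SMR) summaries and maps. Includes a synthetic-data generator
    emulating municipality-level census and death-certificate data with
    known ground truth, so every stage of the analysis is testable
    without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
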
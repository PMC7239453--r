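Package: gosmooth
Title: Goodness-of-Smoothing Diagnostics for Bayesian Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Leroux and Besag-York-Mollie (BYM) conditional
    autoregressive models for areal disease counts by Metropolis-within-Gibbs
    MCMC, and scores competing model variants for under- and over-smoothing.
    Provides five goodness-of-smoothing statistics (ratio of areal variograms
    on boundary-crossing distance, spatial kurtosis preservation, Cohen's
    kappa between quantile-categorised covariate-adjusted incidence ratios,
    fraction of spatial variation, and the relative position of the
    covariate-adjusted standardised incidence ratio between its raw value and
    its neighbourhood mean), alongside classical goodness-of-fit criteria
    (DIC, WAIC, conditional predictive ordinates, Moran's I on residuals),
    with PASS/FAIL cut-off profiles and a consensus summary across model
    variants. Includes readers and writers for GAL weights files, edge lists
    and GeoJSON polygon contiguity, and a synthetic areal-data generator with
    known ground-truth smoothness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
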
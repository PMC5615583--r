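Package: dsfm
Title: Dynamic Spatial Factor Models for Speciated PM2.5 and Correlated
    Binary Birth Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian modelling of multi-pollutant monitoring-network
    data and case-control birth-defect outcomes.  Speciated fine particulate
    matter observed at two monitoring networks (urban STN, rural IMPROVE) is
    described by a multivariate dynamic spatial factor model: a dynamic
    linear model whose latent factors, factor loadings and autoregressive
    propagation coefficients all vary smoothly over space as Gaussian
    processes.  The latent factors are interpolated by Gaussian-process
    conditioning to each mother's residence for gestational weeks 3-8 and
    linked to cleft lip and cleft palate indicators through a bivariate
    probit model with smoothly varying weekly exposure coefficients.
    Fitting is by a Gibbs sampler built on forward-filtering
    backward-sampling, probit data augmentation, elliptical slice sampling
    and conjugate updates; the number of factors is compared by DIC.  A
    synthetic-data module emulates the monitoring networks and cohort so
    the whole pipeline runs without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
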
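Package: velohrv
Title: Heart Rate Variability and Personal Exposure Doses in Pre/Post
    Cycling Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for panel studies of short-term cardiac effects of
    traffic-related particulate matter and noise. Cleans and segments
    RR-interval recordings, computes time- and frequency-domain heart
    rate variability metrics (HR, SDNN, pNN50, rMSSD, LF, HF, LF/HF),
    accumulates inhaled particulate doses from minute ventilation and
    percentage noise doses from per-minute A-weighted levels, pairs
    pre/post rest periods into delta outcomes, and fits Bayesian linear
    models with MA(1) residual autocorrelation by a Metropolis-within-
    Gibbs sampler, reporting credible intervals and Savage-Dickey Bayes
    factors. Includes a seed-reproducible synthetic-study generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
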
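Package: nbdecide
Title: Bayesian Net-Benefit Decision Analysis for Pandemic Reopening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the decision to relax pandemic suppression measures
    ("decremental suppression") through a probabilistic net-benefit rule.
    Fits Bayesian autoregressive regressions with exogenous infection-rate
    covariates to weekly employment and daily fatality-rate series via a
    Metropolis-within-Gibbs sampler, selects the autoregressive order by
    posterior model probability (Laplace-Metropolis evidence), converts
    posterior predictive draws into per-capita income benefits and
    medical-plus-fatality costs under value-of-statistical-life assumptions,
    simulates the distribution of the change in net benefit, and evaluates
    the rule "reopen when the expected change is positive and the probability
    of a positive change exceeds a risk threshold" across policy scenario
    look-up tables. Includes seed-deterministic generators for synthetic
    employment and epidemic count panels with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
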
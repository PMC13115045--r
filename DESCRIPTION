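Package: llpredict
Title: Prediction of Future Failure Times for the Log-Logistic Distribution
    Under Progressive Type-II Censoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequentist and Bayesian inference for the two-parameter
    Log-Logistic (Fisk) lifetime distribution observed under progressive
    Type-II censoring, together with one-sample prediction of the failure
    times of units withdrawn during the experiment.  Provides the
    distribution kernel, progressive censoring scheme construction and
    sampling, maximum likelihood estimation via a log-space Newton-Raphson
    procedure with Herd-Johnson/OLS initialisation, Metropolis-Hastings
    within Gibbs posterior sampling under Jeffreys or empirical Gamma
    priors, three point predictors (best unbiased, conditional median,
    Bayesian), three prediction intervals (pivotal, equal-tailed, highest
    posterior density), Monte Carlo performance studies, and goodness-of-fit
    screening against Weibull, Lognormal and Exponential alternatives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
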
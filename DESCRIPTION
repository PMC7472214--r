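Package: betabandit
Title: Bayesian-Observer Modelling of Restless Two-Armed Bandit Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a restless two-armed bandit task with Gaussian
    random-walk reward probabilities, implements a Bayesian-observer
    learning model (beta-distribution beliefs with forgetting, an
    exploration bonus on posterior variance, and a relative-confidence
    term, combined through a softmax choice rule), fits it by maximum
    likelihood with BIC model comparison against a Rescorla-Wagner
    baseline, extracts trial-by-trial value regressors and performance
    summaries, generates synthetic subject cohorts with a configurable
    covariate path structure, and provides the group-level statistical
    battery (correlations with Fisher confidence intervals, standardized
    multiple regression with variance inflation factors, BIC-based model
    comparison, and group contrasts with Cohen's d).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
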
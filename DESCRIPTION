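Package: hbddm
Title: Hierarchical Bayesian Drift Diffusion Modelling of Cognitive and Motor Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissociating cognitive processing speed (drift rate) from
    motor speed (non-decision time) with the two-boundary drift diffusion model.
    Provides the Wiener first-passage-time likelihood with across-trial
    variability and a uniform-contaminant mixture, a synthetic-data generator for
    a 2x2 spring-pressure by set-size within-subject design, trial- and
    participant-level preprocessing rules, hierarchical Bayesian estimation of a
    nine-model parameter-by-condition space via adaptive Metropolis-within-Gibbs,
    DIC/BPIC model comparison, credible-interval independence checks,
    posterior-predictive response-time quantile checks, and behavioral
    Bayes-factor and correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
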
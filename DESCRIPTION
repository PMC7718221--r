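Package: cleanerclient
Title: Consistent and Dynamic Predictors of Cleaner-Client Mutualism Behaviour
Version: 0.1.0
Authors@R: person("cleanerclient", "developers", email = "cleanerclient@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse long-term observational data on cleaner-client
    mutualisms (e.g. cleaner gobies and their reef-fish clients). Provides a
    seeded synthetic-data generator that emulates multi-year focal-observation
    studies at fixed cleaning stations; random-intercept generalised linear
    mixed models with binomial-probit and log-link Gaussian families fitted by
    penalised iteratively reweighted least squares (the fast nAGQ = 0 mode);
    likelihood-ratio based backward/forward stepwise refinement with
    added-last adjusted pseudo-R-squared importance; a subsample-refit
    consistency classifier that separates consistent from dynamic predictors
    across repeated model simulations; and spatial analyses (Mantel
    permutation tests, station aggregation PC1 scores, relative standard
    errors of station-level predictions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
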
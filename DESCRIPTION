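Package: bfmeta
Title: Bayes Factors and Pooled Estimation for Meta-Analyses Combining
    Randomized and Non-Randomized Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether randomized controlled trials (RCT)
    and non-randomized studies (NRS) should be pooled in a meta-analysis of
    binary outcomes.  Implements frequentist pooled estimation
    (DerSimonian-Laird, Hartung-Knapp-Sidik-Jonkman, and the
    inverse-variance heterogeneity model), a Bayesian normal-normal
    hierarchical model with half-normal or half-Cauchy heterogeneity priors
    solved by deterministic numerical integration, Bayes-factor model
    selection between pooled and design-separate models, posterior model
    probabilities, model-averaged shortest credible intervals, and the
    classification of agreement between frequentist confidence intervals
    and Bayesian credible intervals in excluding the null.  A seeded
    generator of RCT+NRS meta-analytic cohorts supports simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
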
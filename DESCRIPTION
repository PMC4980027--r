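Package: gesbayes
Title: Trend-Sensitive Bayesian Assessment of Good Environmental Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aggregates independent environmental indicator time series into a
    single, trend-sensitive Bayesian probability of Good Environmental Status
    (GES). Per indicator and year, a censored-data likelihood converts the
    sampling distribution of the indicator mean into a probability of passing
    its target; a sequential two-state Bayes update with prior chaining turns
    these into a posterior probability of GES that remembers the former state.
    Also provides the one-out-all-out rule and its type-II-error cost curve,
    weighted additive utility aggregation, normalization diagnostics,
    correlation-matrix PCA and redundancy analysis for a posteriori indicator
    selection with explained-variance accounting, a partial-correlation
    conditional-independence screen, and a latent-factor synthetic indicator
    generator for scenario studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
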
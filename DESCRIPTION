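Package: phenogamm
Title: Binomial Generalized Additive Mixed Models for Fruiting Phenology Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Disentangles long-term trends, local anomalies, and seasonality
    in monthly presence-absence phenology panels of marked plants. Provides a
    penalized regression spline engine for binomial logit additive models with
    cyclic seasonal smooths, per-plant random intercepts and lag-1 serial
    dependence, maximum-likelihood smoothing-parameter selection, Bayesian
    credible bands and Wald tests for smooth terms, a two-step model-selection
    procedure over nested trend/seasonality structures, hidden Markov
    imputation of missing monthly fruit states, per-species qualitative trend
    classification, and simulation tools for studying P-value reliability and
    credible-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    lme4,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
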
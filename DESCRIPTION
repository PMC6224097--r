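Package: mpits
Title: Multilevel Modified-Poisson Interrupted Time Series for Policy
    Evaluation of Delivery-Fee Subsidies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of a national
    delivery-fee subsidy using survey birth histories. Simulates
    DHS-like hierarchical birth records, fits segmented multilevel
    log-link Poisson ("modified Poisson") models for binary outcomes
    with cluster-level random intercepts and random coefficients via
    adaptive Gauss-Hermite quadrature and Laplace approximation,
    adjusts standard errors for regional clustering with a sandwich
    estimator, and produces population-standardized rate ratios and
    rate differences over post-policy horizons with delta-method
    confidence intervals, under alternative exposure-definition
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
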
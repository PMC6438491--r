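Package: lcident
Title: Identification of Latent Class Models from Intervention Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying statistical identifiability of the binary
    two-class, two-item latent class model. Implements the forward map from
    class prevalence and conditional response probabilities to observable
    cell probabilities, seeded simulation of observational and
    post-intervention regimes sharing their conditionals, a multistart
    moment-equation solver that recovers all parameters up to the latent
    label swap once intervention data are added, degrees-of-freedom (Jacobian
    rank) accounting, traversal of the two-dimensional observational solution
    manifold, grid-based Bayesian posteriors demonstrating prior dependence
    without interventions and its removal with them, a hyperprior estimated
    through a coupling of pre- and post-intervention prevalence, and a
    minimal discrete causal Bayesian network layer with stochastic
    intervention surgery and structure discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
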
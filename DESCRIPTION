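Package: bayesicc
Title: Bayesian Hierarchical Intraclass Correlation for Bounded Rating Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inter-rater intraclass correlation (ICC) for observer-rated
    instruments scored on a bounded scale, estimated with a Bayesian
    hierarchical model whose within-encounter variance follows a binomial
    (Bernoulli) variance function sigma^2 * theta * (1 - theta). Observations
    and latent trait levels are modelled with truncated normal distributions
    on (0, 1); studies contribute their own means and variance components.
    Provides a Metropolis-within-Gibbs sampler (conjugate Gibbs steps where
    exact, slice sampling elsewhere), the full family of ICC functionals
    (pointwise, population-averaged, and marginal/pooled across studies),
    classical one-way ANOVA ICC baselines, an empirical variance-function
    diagnostic, convergence diagnostics, and a synthetic-data generator that
    draws rating datasets from the generative model with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
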
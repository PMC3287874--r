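Package: devidence
Title: Posterior Deviance Evidence for Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrated Bayesian/likelihood association analysis for
    case-control genetic data.  Samples the posterior distribution of
    logistic-regression coefficients under near-flat priors with a
    random-walk Metropolis algorithm, summarises the induced posterior
    distributions of deviance and deviance difference (median, central
    95% credible interval, proportion of positive differences), and
    compares the resulting evidence measure against standard
    logistic-regression p-values in replicate-level power studies.
    Includes a synthetic cohort generator emulating a mini-exome style
    case-control study of rare variants (quantitative risk factors, a
    latent liability trait, smoking-modified genetic effects) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
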
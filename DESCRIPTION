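Package: contrep
Title: Continuous-Reputation Dynamics of Indirect Reciprocity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the stability of cooperation under indirect
    reciprocity when reputations and actions are continuous variables on the
    unit interval. Provides trilinear/bilinear interpolation of binary social
    norms (including the leading eight), deterministic mean-field dynamics of
    the image matrix with linear-stability analysis (Jacobian, eigenvalue
    spectrum, and the Q recovery criterion), perturbative mutant analysis
    (first-order and finite-fraction closed forms, payoff differences,
    benefit-cost threshold, and numeric and second-order oracles), and a
    seeded stochastic agent-based simulator of the donation game with
    observation probability, perception error, and implementation error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
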
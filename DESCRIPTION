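Package: nnbayes
Title: Bayesian Neural Networks with Bayesian Alphabet Priors for Genomic
    Prediction and GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome regression through a single-hidden-layer Bayesian
    neural network in which marker effects on latent intermediate traits carry
    Bayesian Alphabet mixture priors (RR-BLUP, BayesA, BayesB, BayesC-pi,
    Bayesian LASSO) sampled by Gibbs sampling, with the hidden nodes updated by
    Hamiltonian Monte Carlo. Provides genomic prediction from posterior samples
    of genotypic values, window-based genome-wide association statistics
    (posterior inclusion probabilities and window posterior probabilities of
    association), the matching linear Bayesian Alphabet baselines, and a
    simulator for traits with dominance and complementary epistasis.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
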
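Package: tppbayes
Title: Bayesian Sigmoid and Semi-Parametric Models for Thermal Proteome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein melting curves from thermal proteome profiling (TPP)
    experiments. Implements a Bayesian three-parameter sigmoid model and a
    semi-parametric extension that augments the sigmoid mean with a Gaussian
    process deviation term, with treatment-effect detection by posterior model
    probabilities computed from Laplace-Metropolis marginal likelihoods under
    multiplicity-controlling prior model probabilities. Includes the frequentist
    NPARC F-test baseline with empirically estimated effective degrees of
    freedom, posterior predictive checks, PSIS-LOO cross-validation, a
    variance-explained diagnostic for non-sigmoid melting behaviour, and a
    synthetic-data generator for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    numDeriv,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
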
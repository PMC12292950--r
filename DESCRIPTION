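Package: fracpinn
Title: Physics-Informed Inverse Modelling of Time-Fractional Diffusion and
    Fractional Viscoelasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the order and the concentration-dependent generalized
    diffusion coefficient of a time-fractional (Caputo) diffusion equation from
    noisy concentration fields, and calibrates fractional Maxwell viscoelastic
    parameters from stress-relaxation time series, using physics-informed
    neural networks whose residuals are built from the L1 finite-difference
    discretization of the Caputo derivative. Includes the discrete fractional
    operators, a Mittag-Leffler evaluator, implicit forward solvers for
    generating synthetic benchmarks, variance-scaled data and consistency
    losses, joint gradient-based optimization of network weights and physical
    parameters, a noise-robustness experiment harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
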
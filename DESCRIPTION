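Package: odesio
Title: Structural Identifiability and Observability Analysis of ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the structural local identifiability of parameters
    and the observability of states in nonlinear ordinary differential equation
    models, directly from the model equations and without any experimental data.
    Two independent engines are provided: a differential-geometry test that
    builds an observability-identifiability matrix from Lie derivatives of the
    outputs and computes its generic rank, and a probabilistic algebraic test
    that solves a specialized variational system as a truncated power series
    and ranks the Jacobian of the output coefficients. All rank computations
    use exact arithmetic in a prime field. The package ships a model zoo of
    microbial community models (generalized and composite Lotka-Volterra,
    quadratic and Monod-kinetics species-metabolite models, and a phage
    cocktail therapy model), output-configuration enumerators, encoded
    expected classifications, ground-truth oracles (Kalman observability for
    linear systems and symmetry-constructed fixtures), and a command-line
    interface for analysis, reproduction of the reference classifications,
    and self-testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    codetools,
    knitr
Config/testthat/edition: 3
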
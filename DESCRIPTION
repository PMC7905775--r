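Package: lvsoliton
Title: Exact Solitary Solutions to Diffusively Coupled Lotka-Volterra Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and verifies closed-form solitary (soliton-type)
    solutions of arbitrary order to a meta-model of two diffusively coupled
    Riccati/Lotka-Volterra systems. Implements the inverse balancing method:
    forward construction of (system, solution) pairs from free parameter
    choices, recovery of solution parameters from a given system, kink and
    dark/bright base-case solvers for single and multiplicatively coupled
    Riccati equations, and exact symbolic plus numeric verification of
    solutions. All algebra is carried out in arbitrary-precision rational
    arithmetic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
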
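Package: rdmft
Title: Hessian-Based Self-Consistent Optimization of 1-RDM Functionals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-consistent minimization of the Mueller (Buijse-Baerends)
    one-body reduced density matrix functional for closed-shell molecules.
    Natural orbitals are parameterized by an orthogonal exponential and
    occupation numbers by a smooth bounded map with an implicit chemical
    potential, and the energy is minimized by a trust-region (quasi-)Newton
    method robust to indefinite Hessians.  Provides the exact analytic
    gradient and Hessian including the occupation-orbital coupling block, an
    O(N^4) "cheap" Hessian for separable functionals, and a quasi-Newton
    (BFGS) approximation of the expensive remainder formulated in the
    redundant (sqrt(n), U) variable space.  Includes a compact Gaussian
    integral engine (s, p, d shells; STO-3G and cc-pVDZ), a restricted
    Hartree-Fock reference, 1-step and 2-step drivers, and synthetic-integral
    fixtures so all derivative machinery is testable without external
    quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
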
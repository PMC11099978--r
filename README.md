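# rdmft

Self-consistent minimization of the Mueller (Buijse–Baerends) one-body
reduced density matrix functional for closed-shell molecules, built around
the Hessian of the energy.

## The problem

In RDMFT the energy is a functional of the 1-RDM, optimized over natural
orbitals (NOs) and occupation numbers (ONs) under ensemble
N-representability (0 ≤ n_i ≤ 2, Σ n_i = N_e).  Self-consistent RDMFT is
notorious for needing thousands of iterations when ONs and NOs are relaxed
in alternating steps with first-order methods.  This package implements a
second-order alternative for the Mueller functional

    E = Σ_i n_i h_ii + ½ Σ_ij n_i n_j [ii|jj] − ½ Σ_ij √(n_i n_j) [ij|ij]

(chemist-notation integrals; the idempotent limit recovers restricted
Hartree–Fock exactly), with:

* an unconstrained parameterization — ONs through a smooth bounded erf map
  with an implicit chemical potential, NOs through the orthogonal
  exponential `U = exp(X)` expanded about the current iterate;
* the **exact analytic gradient and Hessian** in those variables, including
  the ON–NO coupling block, assembled in the redundant ν-space
  `(√n, vec U)` and pushed through the chain rule;
* an **O(N⁴) "cheap" Hessian** for separable functionals (terms expressible
  through generalized Fock-like contractions `v^J`, `v^K`), plus a
  **ν-space BFGS approximation of the expensive remainder**, gated by a
  prefactor `A = exp(−|Δn|_∞ / τ)`;
* a **trust-region (quasi-)Newton optimizer** with an exact
  (eigendecomposition) subproblem solver robust to indefinite Hessians,
  driving both 1-step (joint) and 2-step (alternating) SCF loops with
  macro-restarts that reset the quasi-Newton memory;
* a compact Gaussian integral engine (McMurchie–Davidson, s/p/d shells,
  embedded STO-3G and cc-pVDZ), a DIIS restricted Hartree–Fock reference,
  and synthetic-integral fixtures so every derivative identity is testable
  without external quantum-chemistry software.

Intended users: method developers studying SCF-RDMFT convergence, and
anyone needing a transparent, fully testable R implementation of
natural-orbital optimization machinery.

## Worked example

```r
library(rdmft)
mol <- builtin_molecule("H2O")            # r(OH) 0.9572 A, 104.52 deg
ao  <- compute_ao_integrals(mol, "cc-pvdz")
sys <- rdmft_system(ao, tag = "H2O")      # runs RHF internally
res <- run_one_step(sys, rdmft_config("one_step", "exact"))
```

Output of the summary lines:

```
RHF total energy:     -76.026772 Ha
Mueller total energy: -76.411854 Ha
Correlation energy:   -0.385082 Ha
Iterations (evals):   46, accepted 36, macro 2
Final gradient norm:  4.32e-07
```

The Mueller functional over-correlates (−0.385 Ha of "correlation" for
water is far beyond the exact ≈ −0.21 Ha — a known trait of the
functional, not a bug), and the frontier occupations come out fractional:

```
Largest fractional occupations below 2:
[1] 1.54407 0.17248 0.13568 0.02676 0.02580 0.01897
```

At the converged point the exact Hessian has no negative eigenvalues in
any block (ON, NO, or coupling-induced):

```
   n_on    n_no n_extra n_total
      0       0       0       0
```

`res$trace` holds one row per objective evaluation (rejected trust-region
steps included) with energy, gradient norm, radius and acceptance — the
raw material for convergence plots.  Switching
`rdmft_config("one_step", "cheap+bfgs_nu")` replaces the O(N⁵) exact
Hessian by the O(N⁴) cheap part plus the ν-space BFGS remainder.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/rdmft-run.R", package="rdmft"))')" \
    --geometry water.xyz --basis cc-pvdz --scheme 1step --hessian exact \
    --trace trace.csv --summary summary.json
```

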
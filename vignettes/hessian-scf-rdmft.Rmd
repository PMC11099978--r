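---
title: "Hessian-driven self-consistent optimization of the Mueller functional"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hessian-driven self-consistent optimization of the Mueller functional}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmft)
```

## The model

One-body reduced density matrix functional theory (RDMFT) writes the
electronic energy as a functional of the 1-RDM $\gamma$, whose eigenvectors
are the natural orbitals (NOs) and eigenvalues the occupation numbers (ONs)
$n_i$.  In the spin-summed restricted setting used here, ensemble
$N$-representability requires $0 \le n_i \le 2$ and
$\sum_i n_i = N_e$.  `rdmft` minimizes the Mueller (Buijse--Baerends)
functional,

$$
E = \sum_i n_i h_{ii} + \tfrac12 \sum_{ij} n_i n_j [ii|jj]
  - \tfrac12 \sum_{ij} \sqrt{n_i n_j}\,[ij|ij],
$$

a *separable* functional: its exchange pairing factorizes as
$f(n_i) f(n_j)$ with $f(n)=\sqrt n$.  The normalization is pinned by the
idempotent limit: at $n_i \in \{0, 2\}$ the expression collapses exactly to
the restricted Hartree--Fock energy (this identity is tested).  The Mueller
functional is convex in $\gamma$ (also property-tested on random
representable pairs), which makes it the cleanest testbed for convergence
studies: any optimization difficulty is attributable to the
parameterization, not to functional pathologies.

## Parameterization

Two constraint sets must be maintained:

* **ONs.** We use a smooth bounded map with an implicit chemical potential,
  $\sqrt{n_i/2} = \Phi(x_i + \mu)$ with $\Phi(t) = (1+\operatorname{erf} t)/2$,
  i.e. $n_i = 2\,\Phi(x_i+\mu)^2 \in (0,2)$, where $\mu$ is solved so that
  $\sum_i n_i = N_e$ (safeguarded Newton after bracketing; residual below
  $10^{-12}$).  Because the functional depends on $\sqrt n$, the map is
  built so that $\sqrt{n}$ --- not just $n$ --- is smooth in $x$ with
  bounded derivatives as $n \to 0$; otherwise the gradient diverges at the
  boundary.  The map has one exact gauge direction: shifting every $x_i$ by
  a constant is absorbed by $\mu$, so the Jacobian $\partial n/\partial x$
  annihilates $\mathbf 1$ and every column sums to zero.  The redundancy is
  left in place (the trust-region solver is indifferent to an exactly flat
  direction).
* **NOs.** Orbitals are updated by an orthogonal exponential,
  $C^{(k)} = C^{(k-1)} \exp(X)$ with $X$ antisymmetric.  Derivatives of
  $\exp(X)$ are simple only at $X = 0$, so the expansion point is moved
  after every accepted step ("recentering"); successive generators do not
  add because rotations do not commute.

The optimization variables are $\mathbf x = (x, X^{\mathrm{up}})$ with
$X^{\mathrm{up}}$ the strictly upper triangle of $X$ in row-major order,
$M = N(N-1)/2$ rotation parameters for $N$ basis functions.

## Derivatives: the $\nu$-space route

All derivatives are first assembled in the redundant space
$\nu = (w, \mathrm{vec}\,U)$ with $w_i = \sqrt{n_i}$ and $U$ the full
$N \times N$ rotation, where the energy is polynomial
(for Mueller, quartic in $U$ and quadratic in $w$ per term), and then
pushed to $\mathbf x$-space by the chain rule

$$
H_{\mathbf x} = J^\top H_\nu J
  + \sum_a (g_\nu)_a \, \frac{\partial^2 \nu_a}{\partial \mathbf x^2},
\qquad J = \frac{\partial \nu}{\partial \mathbf x}.
$$

The only two-electron intermediates the gradient needs are the generalized
Fock-like matrices
$v^J_{pq} = \sum_j n_j [pq|jj]$ and $v^K_{pq} = \sum_j \sqrt{n_j}\,[pj|qj]$,
so a gradient costs $O(N^4)$.  The exact Hessian additionally needs
individual MO two-electron integrals $[pi|qj]$, hence the $O(N^5)$
four-index transformation dominates.  Both gradient and Hessian (all three
blocks, including the ON--NO coupling) are validated against central
finite differences of the local-chart energy on random synthetic systems
and real molecules; the finite-difference Hessian differences the *energy*,
not the gradient, because gradients at two different expansion points live
on different charts.

## The cheap/expensive split and the quasi-Newton remainder

For separable functionals the $\nu$-space second derivatives split term by
term:

* **cheap**: every term expressible through $h$, $v^J$, $v^K$, plus the
  whole gradient-level curvature contraction of the chain rule.  This part
  costs no more than the gradient ($O(N^4)$).  Its rotation-rotation block
  entry for generator pairs $(i,j)$, $(p,q)$ vanishes exactly when
  $\{i,j\} \cap \{p,q\} = \emptyset$.
* **expensive**: the terms that need individual MO integrals
  ($4 n_i n_j [pi|qj] - 2\sqrt{n_i n_j}([pq|ij] + [pj|iq])$ in the
  $UU$ block, with analogous $wU$ and $ww$ terms).

`cheap_hessian() + expensive_hessian() = exact_hessian()` holds to machine
precision by construction and is asserted elementwise in the tests.  Where
exactly the block boundary falls inside the occupation block (whether the
$4 w_i w_j [ii|jj] - [ij|ij]$ cross terms count as cheap) is a design
choice; they are classified expensive here because no $v$-type contraction
produces individual $[ii|jj]$ or $[ij|ij]$ entries in $O(N^4)$.

The expensive remainder is approximated by a BFGS matrix
$B_\nu \approx H^{\mathrm{exp}}_\nu$ kept in $\nu$-space, where the true
Hessian is polynomial and far better behaved than in $\mathbf x$-space.
The secant pair is transformed so that closeness is imposed in $\nu$-space
while the secant equation holds in $\mathbf x$-space: the step is pushed
forward, $s_\nu = J s$, and the expensive gradient difference
$y^{\mathrm{exp}} = \Delta g - H^{\mathrm{cheap}} s$ is lifted through the
pseudoinverse, $y_\nu = J (J^\top J)^{+} y^{\mathrm{exp}}$ (the
pseudoinverse is forced by the occupation gauge direction, along which
genuine gradient differences vanish).  After the standard BFGS update with
$(s_\nu, y_\nu)$, the $\mathbf x$-space secant
$J^\top B_\nu J\, s = y^{\mathrm{exp}}$ holds exactly; the tests verify
this and also that feeding the *exact* expensive $\nu$-Hessian through the
assembly reproduces $H^{\mathrm{exa}} - H^{\mathrm{cheap}}$ to $10^{-8}$
relative.

Because gradients at successive expansion points live on different charts,
the secant data are only first-order consistent across a recentering; no
parallel transport is applied.  The macro-restart (below) clears the memory
whenever the approximation has drifted.

The quasi-Newton correction is gated by a prefactor
$A(s_n, \tau) = \exp(-|s_n|_\infty / \tau)$ with $s_n$ the occupation-number
step and $\tau = 10^{-3}$ (occupation units): while occupations still move
substantially the model trusts only the cheap part ($A \approx 0$,
reproducing the plain $B = H^{\mathrm{cheap}}$ behavior of the early
iterations), and switches the memory on as the occupation step collapses.
The model Hessian is
$B_{\mathbf x} = H^{\mathrm{cheap}}_{\mathbf x} + A \, J^\top B_\nu J$.

## Trust-region optimizer

The energy landscape in $X$ is nonconvex even for a convex functional, so
the Hessian is routinely indefinite (the negative-eigenvalue diagnostics
per block are exposed via `count_negative_eigenvalues()`; at any converged
1-step minimum the count is zero, which is asserted on H2O/cc-pVDZ).  The
subproblem $\min_{\|p\| \le \Delta} g^\top p + \tfrac12 p^\top H p$ is
solved exactly through the eigendecomposition of $H$ (secular equation with
hard-case handling); a truncated-CG (Steihaug) alternative is available for
larger problems.  Defaults: initial radius 1.0, shrink $\times 0.25$ below
ratio 0.25, grow $\times 2$ above 0.75 on the boundary, and **acceptance
threshold 0.25** --- acceptance coincident with the shrink threshold, the
strict convention of Coleman--Li-type reflective solvers.  The strict
threshold matters here: occupations saturating towards 0 or 2 create
extremely flat valleys (the $\Phi$ tails are doubly exponential), and a
permissive threshold lets poorly modelled steps be accepted while the
radius collapses, stranding the approximate-Hessian runs a few times
$10^{-8}$ Hartree above the exact-Hessian endpoint.  With strict acceptance
the poor steps are rejected, the radius stays workable, and the cheap part
of the model (whose occupation-block diagonal is exact at the $v^J/v^K$
level) drives the saturation crawl to the same endpoint the exact Hessian
reaches.

Every objective evaluation --- including rejected steps --- counts as one
iteration, matching the accounting used for all iteration numbers quoted
by this package.

## Drivers

* **1-step** (`run_one_step()`): joint minimization over
  $(x, X^{\mathrm{up}})$; the coupling block can be zeroed
  (`coupling = "off"`) for diagnostics.  On micro-convergence
  ($\|g\|_2 < 10^{-6}$ by default) the macro loop checks
  $|\Delta E| < 10^{-8}$ Hartree and otherwise restarts from the current
  point with the quasi-Newton memory reset.
* **2-step** (`run_two_step()`): alternating full ON and NO phases, each to
  the micro tolerance, with the same Hessian machinery restricted to the
  corresponding diagonal block.  It consistently needs more iterations than
  the 1-step scheme (the per-phase plateaus are visible in the trace),
  which is the motivation for the joint update.

Initialization uses the Hartree--Fock orbitals and a Fermi--Dirac-like
occupation distribution $n_i = 2/(1 + e^{\beta(\varepsilon_i - \mu_0)})$
with $\mu_0$ solved for the trace.  The default
$\beta = 10\,\mathrm{Ha}^{-1}$ gives visibly fractional frontier
occupations for double-zeta molecules without starting on top of the
idempotent boundary; the inverse map clips occupations to
$[10^{-15}, 2 - 10^{-15}]$ to keep $x$ finite.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `gtol` | 1e-6 | Hartree (gradient 2-norm) | micro termination |
| `etol` | 1e-8 | Hartree | macro energy-change termination |
| `beta` | 10 | Hartree^-1 | initial occupation temperature |
| `tau` | 1e-3 | occupation units | prefactor decay scale |
| `eta_accept` | 0.25 | -- | trust-region acceptance ratio |
| `initial_radius` | 1.0 | -- | trust radius |
| `mu_tol` | 1e-12 | electrons | trace-constraint residual |

## Synthetic fixtures: what they do and do not show

`synthetic_integrals()` builds $S = I$, a random symmetric one-electron
matrix, and an ERI tensor $\sum_k w_k (v_k v_k^\top) \otimes (v_k v_k^\top)$
with $w_k > 0$ --- exactly 8-fold permutation-symmetric with a
positive-semidefinite Coulomb metric, and bit-reproducible from the seed.
These fixtures have realistic *algebraic structure* (which is all the
derivative machinery sees), so gradient/Hessian/split/secant identities
tested on them transfer to real integrals verbatim.  They do **not**
emulate the spectral structure of molecules (core/valence separation,
near-degeneracies, basis-set linear dependence) or realistic correlation
strength, so convergence-rate observations on them say nothing about real
molecules; all iteration-count checks therefore run on real cc-pVDZ
integrals from the built-in engine.

The integral engine itself (McMurchie--Davidson Hermite scheme, s/p/d
shells, spherical d functions, embedded STO-3G and cc-pVDZ parameters) is
validated against literature restricted Hartree--Fock energies: H2/STO-3G
at 1.4 bohr matches the classic textbook value to $10^{-4}$ Hartree, and
H2O, CH4, HF in cc-pVDZ reproduce standard reference energies to a few
$10^{-4}$ Hartree or better.

## Numerical choices

* $\mu$ solve: bracketed `uniroot` to $10^{-14}$, then Newton polish; the
  trace function is strictly monotone in $\mu$.
* Matrix exponential: dense Pade (`Matrix::expm`); the complex
  eigendecomposition of $iX$ serves as the independent oracle in tests.
* Finite-difference defaults: $10^{-4}$ (gradient), $10^{-3}$ (Hessian),
  central formulas.
* Rotations between degenerate-occupation orbitals leave the energy
  invariant; the resulting zero-curvature directions are left to the
  trust-region solver rather than projected out.
* Negative-eigenvalue counting uses a relative threshold
  ($\lambda < -10^{-10} \max(1, \|H\|_\infty)$ by default) so exact zero
  modes (gauge and degeneracy directions) are not miscounted.
* Orthonormality is monitored at every recentering; drift beyond $10^{-8}$
  triggers symmetric re-orthonormalization with a warning (in practice the
  exponential map keeps drift near $10^{-14}$ over hundreds of steps).

## Problem sizes

The test suite exercises synthetic systems at $N = 4$--$6$ plus STO-3G
molecules for every identity and property, and runs the full desk-scale
convergence checks (1-step exact and cheap+BFGS-$\nu$ on H2O, CH4, HF in
cc-pVDZ, $N = 19$--$34$, joint dimension up to 595) in about a minute on
one CPU.  `scripts/acceptance.R` repeats those three-molecule runs from
scratch and reports the iteration counts to fixed energy errors.

## Known limitations

* Closed-shell, real orbitals, in-core ERIs ($N \lesssim 80$); no density
  fitting, no periodic systems.
* Only separable functionals are implemented; the registry currently holds
  Mueller.  Non-separable families (BBC, PNOF) would invalidate the
  $O(N^4)$ split and are out of scope.
* The secant data are not parallel-transported across expansion points;
  the macro-restart compensates in practice.
* Iteration counts are geometry- and initialization-sensitive; the
  built-in geometries are standard experimental equilibrium structures,
  and any XYZ input is accepted.
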
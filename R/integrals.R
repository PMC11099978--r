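#' Atomic-orbital integrals for a molecule
#'
#' Computes the overlap matrix S, the core Hamiltonian h (kinetic + nuclear
#' attraction) and the full rank-4 two-electron repulsion tensor
#' `[mu nu|kappa lambda]` (chemist notation, 8-fold permutational symmetry)
#' over a contracted Gaussian basis.  Heavy-atom d shells are used in
#' spherical (5-component) form.  Everything is kept in core; the intended
#' problem sizes are N <= ~80 basis functions.
#'
#' @param mol an `rdmft_molecule`.
#' @param basis basis-set name (see [available_bases()]).
#' @return An object of class `rdmft_ao` with fields `n_basis`, `overlap`,
#'   `core_h`, `eri` (N x N x N x N array), `enuc` (nuclear repulsion,
#'   Hartree), `molecule`, `basis`.
#' @export
compute_ao_integrals <- function(mol, basis) {
  shells <- .build_shells(mol, basis)
  one <- cpp_one_electron(shells, as.numeric(mol$atomic_numbers),
                          mol$coordinates * .angstrom)
  M <- .c2s_matrix(shells, one$S)
  S <- t(M) %*% one$S %*% M
  h <- t(M) %*% (one$T + one$V) %*% M
  eri_cart <- cpp_eri(shells)
  eri <- .four_index_transform(eri_cart, M)
  ao <- structure(
    list(n_basis = ncol(M), overlap = .symmetrize(S), core_h = .symmetrize(h),
         eri = eri, enuc = nuclear_repulsion(mol), molecule = mol,
         basis = tolower(basis)),
    class = "rdmft_ao"
  )
  validate_ao_integrals(ao)
  ao
}

.symmetrize <- function(m) (m + t(m)) / 2

# four-index transform eri[abcd] -> sum C_a'a C_b'b C_c'c C_d'd eri, O(N^5)
# via successive quarter transformations; Cmat columns index the new basis.
.four_index_transform <- function(eri, Cmat) {
  n0 <- dim(eri)[1]
  n1 <- ncol(Cmat)
  g <- eri
  for (k in 1:4) {
    d <- dim(g)
    # contract the first index, then rotate it to the back
    g <- matrix(g, d[1], prod(d[-1]))
    g <- crossprod(Cmat, g)                      # n1 x rest
    g <- array(g, c(n1, d[-1]))
    g <- aperm(g, c(2, 3, 4, 1))
  }
  g
}

#' Validate an AO integral set
#'
#' Checks the container invariants: S symmetric positive definite, h
#' symmetric, ERI finite with 8-fold permutational symmetry.
#'
#' @param ao an `rdmft_ao`.
#' @param tol tolerance on the symmetry residuals.
#' @return `ao`, invisibly; stops on violation.
#' @export
validate_ao_integrals <- function(ao, tol = 1e-10) {
  S <- ao$overlap
  if (max(abs(S - t(S))) > tol) stop("overlap matrix not symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("overlap matrix not positive definite")
  }
  if (max(abs(ao$core_h - t(ao$core_h))) > tol) stop("core_h not symmetric")
  if (!all(is.finite(ao$eri))) stop("non-finite ERI entries")
  g <- ao$eri
  sym_res <- max(abs(g - aperm(g, c(2, 1, 3, 4))),
                 abs(g - aperm(g, c(1, 2, 4, 3))),
                 abs(g - aperm(g, c(3, 4, 1, 2))))
  if (sym_res > 1e-10 * max(1, max(abs(g)))) {
    stop("ERI tensor violates 8-fold permutational symmetry (residual ",
         format(sym_res), ")")
  }
  invisible(ao)
}

#' Synthetic AO integrals and reference (test fixture)
#'
#' Generates a fake but structurally faithful integral set: S = I, a random
#' symmetric core Hamiltonian, and an ERI tensor built as a positive
#' combination of rank-1 symmetric products
#' \eqn{[\mu\nu|\kappa\lambda] = \sum_k w_k v_\mu v_\nu v_\kappa v_\lambda}
#' (exact 8-fold symmetry, positive-semidefinite Coulomb metric).  The
#' "Hartree-Fock" reference is obtained by diagonalizing the core
#' Hamiltonian.  All derivative machinery can be exercised on these fixtures
#' without any quantum-chemistry engine.
#'
#' @param n_basis number of basis functions N.
#' @param n_electrons even electron count, 0 < n_electrons < 2 N.
#' @param seed integer seed; output is bit-reproducible given
#'   `(n_basis, n_electrons, seed)`.
#' @param n_rank1 number of rank-1 terms in the ERI construction.
#' @return list with elements `ao` (an `rdmft_ao`) and `rhf` (an
#'   `rdmft_rhf`).
#' @export
synthetic_integrals <- function(n_basis, n_electrons, seed = 1L,
                                n_rank1 = 2L * n_basis) {
  n <- as.integer(n_basis)
  ne <- as.integer(n_electrons)
  if (ne <= 0 || ne >= 2 * n) {
    stop("need 0 < n_electrons < 2*n_basis, got ", ne, " with N = ", n)
  }
  if (ne %% 2 != 0) stop("n_electrons must be even")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  h <- matrix(rnorm(n * n), n, n)
  h <- (h + t(h)) / 2
  eri <- array(0, c(n, n, n, n))
  for (k in seq_len(n_rank1)) {
    v <- rnorm(n)
    w <- runif(1, 0.05, 0.5) / n_rank1
    vv <- tcrossprod(v)
    eri <- eri + w * outer(vv, vv)
  }
  ao <- structure(
    list(n_basis = n, overlap = diag(n), core_h = h, eri = eri, enuc = 0,
         molecule = NULL, basis = "synthetic"),
    class = "rdmft_ao"
  )
  eig <- eigen(h, symmetric = TRUE)
  C0 <- eig$vectors
  eps <- eig$values
  nocc <- ne %/% 2
  D <- 2 * tcrossprod(C0[, seq_len(nocc), drop = FALSE])
  Jm <- .coulomb_matrix(eri, D)
  Km <- .exchange_matrix(eri, D)
  F <- h + Jm - Km / 2
  e_elec <- 0.5 * sum(D * (h + F))
  rhf <- structure(
    list(mo_coefficients = C0, orbital_energies = eps,
         total_electronic_energy = e_elec, e_total = e_elec, enuc = 0,
         converged = TRUE),
    class = "rdmft_rhf"
  )
  list(ao = ao, rhf = rhf)
}

# J(D)_uv = sum_kl D_kl [uv|kl];  K(D)_uv = sum_kl D_kl [uk|vl]
.coulomb_matrix <- function(eri, D) {
  n <- dim(eri)[1]
  matrix(matrix(eri, n * n, n * n) %*% as.vector(D), n, n)
}

.exchange_matrix <- function(eri, D) {
  n <- dim(eri)[1]
  g <- aperm(eri, c(1, 3, 2, 4))
  matrix(matrix(g, n * n, n * n) %*% as.vector(D), n, n)
}

# save/restore global RNG state so fixture generation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
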
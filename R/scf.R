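#' Restricted Hartree-Fock reference
#'
#' Plain closed-shell RHF with DIIS convergence acceleration, used as the
#' starting point (orbitals and orbital energies) for the 1-RDM functional
#' optimization and as an independent energy check in the idempotent limit.
#'
#' @param ao an `rdmft_ao`.
#' @param n_electrons even electron count; defaults to the molecule's.
#' @param conv convergence threshold on the DIIS error norm and energy change.
#' @param max_iter maximum SCF cycles.
#' @return An object of class `rdmft_rhf`: `mo_coefficients` (C0, with
#'   C0' S C0 = I), `orbital_energies`, `total_electronic_energy` (Hartree),
#'   `e_total` (electronic + nuclear), `enuc`, `converged`.
#' @export
run_rhf <- function(ao, n_electrons = NULL, conv = 1e-10, max_iter = 200L) {
  if (is.null(n_electrons)) {
    if (is.null(ao$molecule)) stop("n_electrons required for synthetic integrals")
    n_electrons <- ao$molecule$n_electrons
  }
  n <- ao$n_basis
  nocc <- n_electrons %/% 2
  S <- ao$overlap
  h <- ao$core_h
  se <- eigen(S, symmetric = TRUE)
  X <- se$vectors %*% diag(1 / sqrt(se$values), n) %*% t(se$vectors)

  dens <- function(C) 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  fock <- function(D) h + .coulomb_matrix(ao$eri, D) - .exchange_matrix(ao$eri, D) / 2

  # core-Hamiltonian guess
  Fp <- t(X) %*% h %*% X
  e <- eigen(.symmetrize(Fp), symmetric = TRUE)
  C <- X %*% e$vectors
  D <- dens(C)
  e_old <- Inf
  err_list <- list()
  fock_list <- list()
  converged <- FALSE
  eps <- e$values

  for (it in seq_len(max_iter)) {
    F <- fock(D)
    e_elec <- 0.5 * sum(D * (h + F))
    err <- F %*% D %*% S - S %*% D %*% F
    err <- t(X) %*% err %*% X
    if (max(abs(err)) < conv && abs(e_elec - e_old) < conv) {
      converged <- TRUE
    }
    # DIIS (keep up to 8 vectors)
    err_list[[length(err_list) + 1]] <- err
    fock_list[[length(fock_list) + 1]] <- F
    if (length(err_list) > 8) {
      err_list <- err_list[-1]
      fock_list <- fock_list[-1]
    }
    m <- length(err_list)
    if (m > 1) {
      B <- matrix(-1, m + 1, m + 1)
      B[m + 1, m + 1] <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) {
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      }
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce(`+`, Map(`*`, fock_list, cf))
      }
    }
    Fp <- t(X) %*% F %*% X
    e <- eigen(.symmetrize(Fp), symmetric = TRUE)
    idx <- order(e$values)
    eps <- e$values[idx]
    C <- X %*% e$vectors[, idx, drop = FALSE]
    D <- dens(C)
    if (converged) break
    e_old <- e_elec
  }
  F <- fock(D)
  e_elec <- 0.5 * sum(D * (h + F))
  ortho <- max(abs(t(C) %*% S %*% C - diag(n)))
  if (ortho > 1e-10) stop("RHF orbitals not S-orthonormal (residual ", ortho, ")")
  structure(
    list(mo_coefficients = C, orbital_energies = eps,
         total_electronic_energy = e_elec, e_total = e_elec + ao$enuc,
         enuc = ao$enuc, converged = converged, n_electrons = n_electrons),
    class = "rdmft_rhf"
  )
}
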
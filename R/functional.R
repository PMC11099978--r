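# Separable 1-RDM functionals F(n_i, n_j) = f(n_i) f(n_j) on the exchange
# integrals, with the Hartree channel weighted by n_i n_j.  Spin-summed
# restricted convention (0 <= n <= 2):
#   E = sum_i n_i h_ii + 1/2 sum_ij n_i n_j J_ij - 1/2 sum_ij f(n_i) f(n_j) K_ij
# For the Mueller (Buijse-Baerends) functional f(n) = sqrt(n), so the
# idempotent limit (n in {0,2}) recovers the RHF energy exactly.

#' Separable functional by name
#'
#' Currently registered: `"muller"` (f(n) = sqrt(n)).  The returned object
#' carries f and its derivatives on the occupation scale, and the same
#' quantities on the w = sqrt(n) scale used internally by the derivative
#' machinery (for Mueller, f(w^2) = w is linear in w, which is why the
#' nu-space Hessian is simple).
#'
#' @param name functional name.
#' @return An object of class `rdmft_functional` with fields `name`,
#'   `f`, `fprime`, `fsecond` (functions of n), and `fw`, `fw1`, `fw2`
#'   (functions of w = sqrt(n)).
#' @export
separable_functional <- function(name = "muller") {
  name <- tolower(name)
  if (name == "muller") {
    out <- list(
      name = "muller",
      f = function(n) sqrt(n),
      fprime = function(n) 0.5 / sqrt(n),
      fsecond = function(n) -0.25 * n^(-1.5),
      fw = function(w) w,
      fw1 = function(w) rep(1, length(w)),
      fw2 = function(w) rep(0, length(w))
    )
    return(structure(out, class = "rdmft_functional"))
  }
  stop("unknown separable functional '", name, "'; registered: muller")
}

#' Transform integrals to the current natural-orbital basis
#'
#' Four-index transformation of the ERI tensor (O(N^5) via quarter
#' transforms) plus the one-electron matrix, and the Coulomb/exchange
#' diagonal slices J_ij = [ii|jj], K_ij = [ij|ij].
#'
#' @param ao an `rdmft_ao`.
#' @param C orbital coefficients with `t(C) S C = I`.
#' @return An object of class `rdmft_mocache` with `h_mo`, `eri_mo`, `J`,
#'   `K`, `n_basis`.
#' @export
transform_integrals <- function(ao, C) {
  N <- ao$n_basis
  ortho <- max(abs(crossprod(C, ao$overlap %*% C) - diag(N)))
  if (ortho > 1e-8) {
    stop("coefficients not S-orthonormal (residual ", format(ortho), ")")
  }
  h_mo <- .symmetrize(crossprod(C, ao$core_h %*% C))
  eri_mo <- .four_index_transform(ao$eri, C)
  idx <- seq_len(N)
  Jm <- matrix(eri_mo[cbind(
    rep(idx, N), rep(idx, N), rep(idx, each = N), rep(idx, each = N))], N, N)
  Km <- matrix(eri_mo[cbind(
    rep(idx, N), rep(idx, each = N), rep(idx, N), rep(idx, each = N))], N, N)
  structure(
    list(h_mo = h_mo, eri_mo = eri_mo, J = .symmetrize(Jm),
         K = .symmetrize(Km), n_basis = N, C = C),
    class = "rdmft_mocache"
  )
}

#' Functional energy from an MO cache and occupations
#'
#' @param cache an `rdmft_mocache` at the current orbitals.
#' @param n occupation vector (0 <= n <= 2, trace = electron count).
#' @param functional an `rdmft_functional`.
#' @return electronic energy in Hartree.
#' @export
rdmft_energy <- function(cache, n, functional = separable_functional("muller")) {
  if (any(n < -1e-12)) stop("negative occupation number")
  n <- pmax(n, 0)
  f <- functional$f(n)
  sum(n * diag(cache$h_mo)) +
    0.5 * sum((n %o% n) * cache$J) -
    0.5 * sum((f %o% f) * cache$K)
}

#' Functional energy from an AO-basis 1-RDM
#'
#' Diagonalizes gamma in the S-orthonormal sense, checks ensemble
#' N-representability of the eigenvalues, and delegates to [rdmft_energy()].
#' Used for convexity property checks.
#'
#' @param ao an `rdmft_ao`.
#' @param gamma symmetric AO-basis 1-RDM (`C diag(n) t(C)` convention).
#' @param functional an `rdmft_functional`.
#' @param tol representability slack on the eigenvalues.
#' @return electronic energy in Hartree.
#' @export
energy_from_gamma <- function(ao, gamma,
                              functional = separable_functional("muller"),
                              tol = 1e-8) {
  S <- ao$overlap
  se <- eigen(S, symmetric = TRUE)
  Shalf <- se$vectors %*% (sqrt(se$values) * t(se$vectors))
  Sminushalf <- se$vectors %*% ((1 / sqrt(se$values)) * t(se$vectors))
  gp <- .symmetrize(Shalf %*% gamma %*% Shalf)
  e <- eigen(gp, symmetric = TRUE)
  n <- e$values
  if (any(n < -tol) || any(n > 2 + tol)) {
    stop("1-RDM not ensemble N-representable: eigenvalues in [",
         format(min(n)), ", ", format(max(n)), "]")
  }
  n <- pmin(pmax(n, 0), 2)
  C <- Sminushalf %*% e$vectors
  cache <- transform_integrals(ao, C)
  rdmft_energy(cache, n, functional)
}

#' Energy of a state
#'
#' Convenience wrapper: transforms the integrals at the state's orbitals and
#' evaluates the functional energy.
#'
#' @param ao an `rdmft_ao`.
#' @param state an `rdmft_state`.
#' @param functional an `rdmft_functional`.
#' @return electronic energy in Hartree.
#' @export
state_energy <- function(ao, state, functional = separable_functional("muller")) {
  cache <- transform_integrals(ao, state$coefficients)
  rdmft_energy(cache, state$occupations, functional)
}
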
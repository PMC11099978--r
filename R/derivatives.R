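# Analytic gradient and exact Hessian of the separable-functional energy
# with respect to the unconstrained variables (x, X^up), at the expansion
# point X = 0.
#
# All derivatives are first formed in the redundant nu-space
# nu = (w, vec(U)), w = sqrt(n), where the energy
#   E(w, U) = sum_i w_i^2 h~_ii + 1/2 sum_ij w_i^2 w_j^2 J~_ij
#             - 1/2 sum_ij fw(w_i) fw(w_j) K~_ij
# is polynomial in U and (for Mueller, fw(w) = w) in w, and then pushed to
# x-space by the chain rule
#   H_x = J' H_nu J + sum_a (g_nu)_a d2 nu_a / dx dx .
# The nu-space second derivatives split term-by-term into a "cheap" part
# expressible through the generalized Fock-like intermediates
#   vJ_pq = sum_j n_j [pq|jj],   vK_pq = sum_j fw_j [pb|qb]-type sums
# (O(N^4) without a full 4-index transformation) and an "expensive"
# remainder that needs individual MO two-electron integrals.

.colscale <- function(M, v) M * rep(v, each = nrow(M))

# nu-space derivative terms at the expansion point (U = I).
# part: "all", "cheap" or "expensive"; want_hessian toggles second derivs.
.nu_terms <- function(cache, n, functional, part = "all",
                      want_hessian = TRUE) {
  N <- cache$n_basis
  w <- sqrt(pmax(n, 0))
  fw <- functional$fw(w)
  fw1 <- functional$fw1(w)
  fw2 <- functional$fw2(w)
  eri <- cache$eri_mo
  eriM <- matrix(eri, N * N, N * N)
  diagidx <- seq_len(N) + (seq_len(N) - 1L) * N
  # vJ_pq = sum_j n_j [pq|jj] ; vK_pq = sum_j fw_j [pj|qj]
  vJ <- matrix(eriM[, diagidx] %*% n, N, N)
  gt <- aperm(eri, c(1, 3, 2, 4))                    # gt[p,q,b,b'] = [pb|qb']
  gtM <- matrix(gt, N * N, N * N)
  vK <- matrix(gtM[, diagidx] %*% fw, N, N)
  hJ <- cache$h_mo + vJ

  # gradient (always full; the term split applies to second derivatives)
  g_w <- 2 * w * diag(hJ) - fw1 * diag(vK)
  G_u <- 2 * .colscale(hJ, n) - 2 * .colscale(vK, fw)

  out <- list(g_w = g_w, G_u = G_u, vJ = vJ, vK = vK, w = w, fw = fw,
              n = n, N = N)
  if (!want_hessian) return(out)

  want_cheap <- part %in% c("all", "cheap")
  want_exp <- part %in% c("all", "expensive")

  Hww <- matrix(0, N, N)
  HwU <- matrix(0, N, N * N)
  HUU <- matrix(0, N * N, N * N)

  if (want_cheap) {
    diag(Hww) <- diag(Hww) + 2 * diag(hJ) - fw2 * diag(vK)
    V <- 4 * w * hJ - 2 * fw1 * vK        # row k: coupling to column-block k
    for (k in seq_len(N)) {
      HwU[k, (k - 1L) * N + seq_len(N)] <-
        HwU[k, (k - 1L) * N + seq_len(N)] + V[k, ]
      blk <- (k - 1L) * N + seq_len(N)
      HUU[blk, blk] <- HUU[blk, blk] + 2 * n[k] * hJ - 2 * fw[k] * vK
    }
  }
  if (want_exp) {
    Jm <- cache$J
    Km <- cache$K
    Hww <- Hww + 4 * tcrossprod(w) * Jm - tcrossprod(fw1) * Km
    # HwU_exp[k,(p,i)] = 4 n_i w_k [pi|kk] - 2 fw_i fw1_k [pk|ik]
    E3a <- eriM[, diagidx]                    # [(p,i), k] = [pi|kk]
    D3 <- gtM[, diagidx]                      # [(p,i), k] = [pk|ik]
    t1 <- 4 * E3a * outer(rep(n, each = N), w)
    t2 <- 2 * D3 * outer(rep(fw, each = N), fw1)
    HwU <- HwU + t(t1 - t2)
    # HUU_exp[(p,i),(q,j)] = 4 n_i n_j [pi|qj] - 2 fw_i fw_j ([pq|ij]+[pj|iq])
    nn <- rep(n, each = N)
    ff <- rep(fw, each = N)
    T1 <- eriM * outer(nn, nn)
    T23 <- matrix(aperm(eri, c(1, 3, 2, 4)) + aperm(eri, c(1, 3, 4, 2)),
                  N * N, N * N) * outer(ff, ff)
    HUU <- HUU + 4 * T1 - 2 * T23
  }
  out$Hww <- Hww
  out$HwU <- HwU
  out$HUU <- HUU
  out
}

# push nu-space second derivatives to x-space; curvature contraction of the
# nu-gradient is added when g_w / G_u are supplied (non-NULL).
.x_hessian_from_nu <- function(Hww, HwU, HUU, map, g_w = NULL, G_u = NULL) {
  N <- map$N; M <- map$M
  W <- map$W
  pairs <- map$pairs
  iab <- pairs[, 1] + (pairs[, 2] - 1L) * N
  iba <- pairs[, 2] + (pairs[, 1] - 1L) * N
  occ <- crossprod(W, Hww %*% W)
  CU <- HwU[, iab, drop = FALSE] - HwU[, iba, drop = FALSE]   # N x M
  cross <- crossprod(W, CU)
  rot <- HUU[iab, iab, drop = FALSE] - HUU[iba, iab, drop = FALSE] -
    HUU[iab, iba, drop = FALSE] + HUU[iba, iba, drop = FALSE]
  H <- matrix(0, N + M, N + M)
  H[seq_len(N), seq_len(N)] <- occ
  H[seq_len(N), N + seq_len(M)] <- cross
  H[N + seq_len(M), seq_len(N)] <- t(cross)
  H[N + seq_len(M), N + seq_len(M)] <- rot
  if (!is.null(g_w)) {
    H <- H + map$curvature_contraction(g_w, G_u)
  }
  .symmetrize(H)
}

.check_cache <- function(state, cache) {
  if (!is.null(cache$C) &&
      max(abs(cache$C - state$coefficients)) > 1e-12) {
    stop("stale MO cache: integrals were transformed at different orbitals")
  }
}

.as_hessian_blocks <- function(H, N, M) {
  structure(
    list(on_block = H[seq_len(N), seq_len(N), drop = FALSE],
         coupling_block = H[seq_len(N), N + seq_len(M), drop = FALSE],
         no_block = H[N + seq_len(M), N + seq_len(M), drop = FALSE],
         full = H, N = N, M = M),
    class = "rdmft_hessian"
  )
}

#' Analytic energy gradient in (x, X^up)
#'
#' Occupation part chains the nu-space gradient through the occupation map
#' (including the implicit chemical-potential response); rotation part is
#' the antisymmetrized orbital-gradient matrix.  Cost O(N^4) given the MO
#' cache.
#'
#' @param state an `rdmft_state` at its expansion point.
#' @param cache `rdmft_mocache` at the state's orbitals.
#' @param functional an `rdmft_functional`.
#' @return An object of class `rdmft_gradient`: `occ_part` (length N),
#'   `rot_part` (length M), `vec` (their concatenation), plus the nu-space
#'   pieces `g_w` and `G_u`.
#' @export
rdmft_gradient <- function(state, cache,
                           functional = separable_functional("muller")) {
  .check_cache(state, cache)
  nt <- .nu_terms(cache, state$occupations, functional, want_hessian = FALSE)
  map <- build_nu_map(state)
  occ <- as.vector(crossprod(map$W, nt$g_w))
  rot <- nt$G_u[state$pairs] - nt$G_u[state$pairs[, c(2, 1), drop = FALSE]]
  structure(
    list(occ_part = occ, rot_part = rot, vec = c(occ, rot),
         g_w = nt$g_w, G_u = nt$G_u),
    class = "rdmft_gradient"
  )
}

#' Exact analytic Hessian in (x, X^up)
#'
#' All three blocks (occupation-occupation, occupation-rotation coupling,
#' rotation-rotation), assembled from the exact nu-space second derivatives
#' by the chain rule.  Needs the full MO two-electron tensor (O(N^5)
#' transformation dominates the cost).
#'
#' @inheritParams rdmft_gradient
#' @return An `rdmft_hessian` with `on_block` (N x N), `coupling_block`
#'   (N x M), `no_block` (M x M) and the assembled symmetric `full` matrix.
#' @export
exact_hessian <- function(state, cache,
                          functional = separable_functional("muller")) {
  .check_cache(state, cache)
  nt <- .nu_terms(cache, state$occupations, functional, part = "all")
  map <- build_nu_map(state)
  H <- .x_hessian_from_nu(nt$Hww, nt$HwU, nt$HUU, map, nt$g_w, nt$G_u)
  .as_hessian_blocks(H, map$N, map$M)
}

#' Energy on the local chart of an expansion point
#'
#' Evaluates the energy at displaced variables `(x + dz_occ, X = dz_rot)`
#' without moving the expansion point.  This is the objective the
#' trust-region model approximates; also the basis for the finite-difference
#' oracles.
#'
#' @param ao an `rdmft_ao`.
#' @param state an `rdmft_state`.
#' @param z displacement, length N + M (occupation part first).
#' @param functional an `rdmft_functional`.
#' @return electronic energy in Hartree.
#' @export
local_energy <- function(ao, state, z,
                         functional = separable_functional("muller")) {
  N <- state$n_basis
  M <- state$n_rot
  dx <- z[seq_len(N)]
  dX <- z[N + seq_len(M)]
  occ <- occupations_from_x(state$occ_params + dx, state$n_electrons)
  U <- rotation_from_X(.unpack_X(dX, N, state$pairs))
  C <- state$coefficients %*% U
  cache <- transform_integrals(ao, C)
  rdmft_energy(cache, occ$n, functional)
}

#' Finite-difference gradient (oracle)
#'
#' Central differences of [local_energy()] over all N + M directions.  Used
#' in tests and diagnostics only.
#'
#' @inheritParams local_energy
#' @param step finite-difference step; values outside `[1e-7, 1e-3]` are
#'   accepted with a warning.
#' @return numeric vector of length N + M.
#' @export
fd_gradient <- function(ao, state,
                        functional = separable_functional("muller"),
                        step = 1e-4) {
  if (step < 1e-7 || step > 1e-3) {
    warning("finite-difference step ", step,
            " outside the recommended [1e-7, 1e-3]; computing anyway")
  }
  dim_tot <- state$n_basis + state$n_rot
  g <- numeric(dim_tot)
  for (k in seq_len(dim_tot)) {
    e <- numeric(dim_tot)
    e[k] <- step
    g[k] <- (local_energy(ao, state, e, functional) -
             local_energy(ao, state, -e, functional)) / (2 * step)
  }
  g
}

#' Finite-difference Hessian (oracle)
#'
#' Central second differences of [local_energy()] on the expansion point's
#' own chart.  Differencing the energy rather than the gradient avoids any
#' chart ambiguity from the noncommutativity of successive rotations (the
#' gradient is only defined at an expansion point, and gradients at two
#' different expansion points live on different charts).
#'
#' @inheritParams local_energy
#' @param step finite-difference step.
#' @return symmetric (N + M) x (N + M) matrix.
#' @export
fd_hessian <- function(ao, state,
                       functional = separable_functional("muller"),
                       step = 1e-3) {
  dim_tot <- state$n_basis + state$n_rot
  H <- matrix(0, dim_tot, dim_tot)
  E0 <- local_energy(ao, state, numeric(dim_tot), functional)
  Ef <- function(z) local_energy(ao, state, z, functional)
  unit <- function(k, s) {
    e <- numeric(dim_tot)
    e[k] <- s
    e
  }
  for (k in seq_len(dim_tot)) {
    H[k, k] <- (Ef(unit(k, step)) + Ef(unit(k, -step)) - 2 * E0) / step^2
    if (k < dim_tot) {
      for (l in (k + 1):dim_tot) {
        epp <- unit(k, step) + unit(l, step)
        epm <- unit(k, step) + unit(l, -step)
        emp <- unit(k, -step) + unit(l, step)
        emm <- unit(k, -step) + unit(l, -step)
        H[k, l] <- H[l, k] <-
          (Ef(epp) - Ef(epm) - Ef(emp) + Ef(emm)) / (4 * step^2)
      }
    }
  }
  H
}

#' Count negative Hessian eigenvalues by block
#'
#' Saddle-point diagnostic: numbers of negative eigenvalues of the
#' occupation block alone, of the orbital-rotation block alone, and the
#' excess of the full matrix over the two blocks (attributable to the
#' coupling; may be negative).
#'
#' @param blocks an `rdmft_hessian`.
#' @param tol eigenvalues below `-tol * max(1, |H|)` count as negative.
#' @return list `n_on`, `n_no`, `n_extra`, `n_total`.
#' @export
count_negative_eigenvalues <- function(blocks, tol = 1e-10) {
  thr <- function(m) {
    if (length(m) == 0) return(0L)
    ev <- eigen(.symmetrize(m), symmetric = TRUE, only.values = TRUE)$values
    sum(ev < -tol * max(1, max(abs(m))))
  }
  n_on <- thr(blocks$on_block)
  n_no <- thr(blocks$no_block)
  n_tot <- thr(blocks$full)
  list(n_on = n_on, n_no = n_no, n_extra = n_tot - n_on - n_no,
       n_total = n_tot)
}
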
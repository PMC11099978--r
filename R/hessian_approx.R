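# Cheap/expensive Hessian split and the nu-space BFGS approximation of the
# expensive remainder.
#
# "Cheap" collects every second-derivative term expressible through the
# one-electron matrix and the generalized Fock-like intermediates vJ/vK
# (computable in O(N^4) without a full 4-index transformation), plus the
# whole gradient-level curvature contraction of the chain rule.  The
# "expensive" remainder needs individual MO two-electron integrals
# ([pi|qj]-type) and is what the quasi-Newton memory approximates.

#' Cheap part of the exact Hessian
#'
#' Exact one-electron part everywhere; two-electron terms restricted to
#' vJ/vK contractions.  Its rotation-rotation block entry for generator
#' pairs (i,j) and (p,q) vanishes whenever the index sets are disjoint.
#'
#' @inheritParams rdmft_gradient
#' @return An `rdmft_hessian`.
#' @export
cheap_hessian <- function(state, cache,
                          functional = separable_functional("muller")) {
  .check_cache(state, cache)
  nt <- .nu_terms(cache, state$occupations, functional, part = "cheap")
  map <- build_nu_map(state)
  H <- .x_hessian_from_nu(nt$Hww, nt$HwU, nt$HUU, map, nt$g_w, nt$G_u)
  .as_hessian_blocks(H, map$N, map$M)
}

#' Expensive remainder of the exact Hessian
#'
#' The complement of [cheap_hessian()]: `H_exp = H_exa - H_cheap` holds
#' elementwise by construction.  Used in tests and error diagnostics, and as
#' the exact reference for the quasi-Newton approximation.
#'
#' @inheritParams rdmft_gradient
#' @return An `rdmft_hessian`.
#' @export
expensive_hessian <- function(state, cache,
                              functional = separable_functional("muller")) {
  .check_cache(state, cache)
  nt <- .nu_terms(cache, state$occupations, functional, part = "expensive")
  map <- build_nu_map(state)
  H <- .x_hessian_from_nu(nt$Hww, nt$HwU, nt$HUU, map, g_w = NULL)
  .as_hessian_blocks(H, map$N, map$M)
}

#' Difference of two Hessian block sets
#'
#' `h_exa - h_cheap`, with a dimension consistency check.
#'
#' @param h_exa,h_cheap `rdmft_hessian` objects built at the same state.
#' @return An `rdmft_hessian`.
#' @export
expensive_remainder <- function(h_exa, h_cheap) {
  if (h_exa$N != h_cheap$N || h_exa$M != h_cheap$M) {
    stop("stale state: Hessian blocks have mismatched dimensions")
  }
  .as_hessian_blocks(h_exa$full - h_cheap$full, h_exa$N, h_exa$M)
}

#' Per-block relative error of an approximate Hessian
#'
#' 1-norm of the entrywise error divided by the number of entries of each
#' block, for the occupation, coupling and rotation blocks (the error
#' diagnostic tracked along an optimization).
#'
#' @param h_ref,h_approx `rdmft_hessian` objects.
#' @return named numeric vector `on`, `coupling`, `no`.
#' @export
hessian_block_errors <- function(h_ref, h_approx) {
  rel <- function(a, b) sum(abs(a - b)) / length(a) / max(1e-300, max(abs(a)))
  c(on = rel(h_ref$on_block, h_approx$on_block),
    coupling = rel(h_ref$coupling_block, h_approx$coupling_block),
    no = rel(h_ref$no_block, h_approx$no_block))
}

#' Standard BFGS update
#'
#' `B' = B - B s s' B / (s' B s) + y y' / (y' s)`; B' is symmetric and
#' satisfies the secant equation `B' s = y` exactly.  The update is skipped
#' (returning B with attribute `skipped = TRUE`) when the curvature products
#' degenerate (`|s'y|` below floor, or `s'Bs = 0` with `Bs != 0`).
#'
#' @param B symmetric matrix.
#' @param s step vector.
#' @param y gradient-difference vector.
#' @param floor relative curvature floor on `|s'y|`.
#' @return updated symmetric matrix.
#' @export
bfgs_update <- function(B, s, y, floor = 1e-12) {
  sy <- sum(s * y)
  if (abs(sy) <= floor * sqrt(sum(s^2)) * sqrt(sum(y^2))) {
    attr(B, "skipped") <- TRUE
    return(B)
  }
  Bs <- as.vector(B %*% s)
  sBs <- sum(s * Bs)
  if (abs(sBs) < 1e-300) {
    if (sqrt(sum(Bs^2)) > 1e-12 * sqrt(sum(s^2)) * max(abs(B))) {
      attr(B, "skipped") <- TRUE
      return(B)
    }
    Bnew <- B + tcrossprod(y) / sy
  } else {
    Bnew <- B - tcrossprod(Bs) / sBs + tcrossprod(y) / sy
  }
  attr(Bnew, "skipped") <- NULL
  .symmetrize(Bnew)
}

#' Create an empty nu-space BFGS memory
#'
#' The memory approximates the expensive nu-space Hessian and starts at
#' zero, so the first model Hessians coincide with the cheap part.
#'
#' @param N basis size.
#' @return An object of class `rdmft_bfgs_memory` (an environment with the
#'   symmetric `(N + N^2)` square matrix `B` and an update counter).
#' @export
bfgs_memory <- function(N) {
  e <- new.env(parent = emptyenv())
  e$N <- N
  e$B <- matrix(0, N + N * N, N + N * N)
  e$n_updates <- 0L
  e$n_skipped <- 0L
  class(e) <- "rdmft_bfgs_memory"
  e
}

#' Reset a nu-space BFGS memory (macro-restart)
#'
#' @param memory an `rdmft_bfgs_memory`.
#' @return the memory, invisibly.
#' @export
bfgs_reset <- function(memory) {
  memory$B[] <- 0
  memory$n_updates <- 0L
  invisible(memory)
}

# structured J s and minimal-norm lift J (J'J)^{-1} y through the x -> nu
# Jacobian; both return full nu-vectors (length N + N^2).
.nu_expand <- function(map, v_occ, v_rot) {
  N <- map$N
  out <- numeric(N + N * N)
  out[seq_len(N)] <- v_occ
  if (map$M > 0) {
    iab <- N + map$pairs[, 1] + (map$pairs[, 2] - 1L) * N
    iba <- N + map$pairs[, 2] + (map$pairs[, 1] - 1L) * N
    out[iab] <- out[iab] + v_rot
    out[iba] <- out[iba] - v_rot
  }
  out
}

#' nu-space BFGS update of the expensive-Hessian memory
#'
#' The secant pair is transformed so that closeness is imposed in nu-space
#' while the secant equation still holds in x-space: the step is pushed
#' forward (`s_nu = J s`) and the expensive gradient difference is lifted
#' through the pseudoinverse (`y_nu = J (J'J)^{-1} y_exp`), after which
#' `J' B_nu J s = y_exp` holds exactly for the updated memory.
#'
#' @param memory an `rdmft_bfgs_memory`.
#' @param s x-space step (length N + M).
#' @param y_exp x-space expensive-part gradient difference (length N + M).
#' @param map the `rdmft_numap` of the expansion point.
#' @return the memory, invisibly (updated in place).
#' @export
nu_bfgs_update <- function(memory, s, y_exp, map) {
  N <- map$N
  if (sqrt(sum(s^2)) == 0) return(invisible(memory))
  s_occ <- s[seq_len(N)]
  s_rot <- s[N + seq_len(map$M)]
  y_occ <- y_exp[seq_len(N)]
  y_rot <- y_exp[N + seq_len(map$M)]
  s_nu <- .nu_expand(map, as.vector(map$W %*% s_occ), s_rot)
  # W'W is singular along the occupation gauge direction (a uniform shift of
  # x is absorbed by the chemical potential, so J 1 = 0); genuine gradient
  # differences have no component there, and the lift uses the pseudoinverse
  WtW <- crossprod(map$W)
  sv <- svd(WtW)
  keep <- sv$d > 1e-12 * max(sv$d)
  q_occ <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y_occ)) / sv$d[keep])
  y_nu <- .nu_expand(map, as.vector(map$W %*% q_occ), y_rot / 2)
  Bnew <- bfgs_update(memory$B, s_nu, y_nu)
  if (isTRUE(attr(Bnew, "skipped"))) {
    memory$n_skipped <- memory$n_skipped + 1L
  } else {
    memory$B <- Bnew
    memory$n_updates <- memory$n_updates + 1L
  }
  invisible(memory)
}

#' Gating prefactor for the quasi-Newton correction
#'
#' `A(s_n, tau) = exp(-|s_n|_inf / tau)`: continuous, 1 when the occupation
#' step vanishes (algorithm has started to converge, quasi-Newton memory
#' trustworthy) and ~0 for large occupation steps (fall back on the cheap
#' Hessian).
#'
#' @param s_n occupation-number step vector.
#' @param tau decay scale (occupation units), default `1e-3`.
#' @return scalar in (0, 1].
#' @export
prefactor <- function(s_n, tau = 1e-3) {
  if (tau <= 0) stop("tau must be positive")
  if (length(s_n) == 0) return(1)
  exp(-max(abs(s_n)) / tau)
}

#' Assemble the approximate x-space Hessian
#'
#' `B_x = H_cheap + A * (J' B_nu J + curvature_contraction(g_nu_exp))`.
#' With the package's term split the expensive part of the nu-gradient is
#' identically zero (the curvature contraction belongs to the cheap part),
#' so `g_nu_exp` defaults to NULL; passing the exact expensive nu-Hessian as
#' `memory$B` with `A = 1` reproduces the exact Hessian.
#'
#' @param h_cheap an `rdmft_hessian` from [cheap_hessian()].
#' @param memory an `rdmft_bfgs_memory`.
#' @param map the `rdmft_numap` of the expansion point.
#' @param g_nu_exp optional list `(g_w, G_u)` of an expensive nu-gradient.
#' @param A scalar gating factor in [0, 1].
#' @return symmetric (N + M) x (N + M) matrix.
#' @export
assemble_approx_hessian <- function(h_cheap, memory, map, g_nu_exp = NULL,
                                    A = 1) {
  N <- map$N
  if (memory$N != N || h_cheap$N != N) stop("dimension mismatch in assembly")
  out <- h_cheap$full
  if (A > 0) {
    iw <- seq_len(N)
    iU <- N + seq_len(N * N)
    Bput <- .x_hessian_from_nu(
      memory$B[iw, iw, drop = FALSE],
      memory$B[iw, iU, drop = FALSE],
      memory$B[iU, iU, drop = FALSE],
      map,
      g_w = if (is.null(g_nu_exp)) NULL else g_nu_exp$g_w,
      G_u = if (is.null(g_nu_exp)) NULL else g_nu_exp$G_u)
    out <- out + A * Bput
  }
  .symmetrize(out)
}
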
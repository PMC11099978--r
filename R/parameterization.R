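# Occupation-number and natural-orbital parameterization.
#
# Occupations use a smooth bounded "explicit-by-implicit" map adapted so that
# sqrt(n) has finite derivatives as n -> 0:
#     sqrt(n_i / 2) = Phi(x_i + mu),   Phi(t) = (1 + erf(t)) / 2,
# i.e. n_i = 2 Phi(x_i + mu)^2 in (0, 2), with the chemical potential mu
# solved implicitly so that sum(n) = N_e.  Orbitals are parameterized by
# U = exp(X) with X antisymmetric, expanded about the current iterate (X = 0
# at each expansion point).

.phi <- function(t) pnorm(sqrt(2) * t)                 # (1 + erf(t))/2
.phi1 <- function(t) exp(-t * t) / sqrt(pi)            # Phi'
.phi2 <- function(t) -2 * t * exp(-t * t) / sqrt(pi)   # Phi''
.phi_inv <- function(p) qnorm(p) / sqrt(2)

# internal: occupation map pieces at a consistent (x, mu)
.occ_pieces <- function(x, mu) {
  t <- x + mu
  phi <- .phi(t)
  phi1 <- .phi1(t)
  phi2 <- .phi2(t)
  list(t = t, phi = phi, phi1 = phi1, phi2 = phi2,
       n = 2 * phi^2, w = sqrt(2) * phi,
       dn_dt = 4 * phi * phi1,                 # d n_i / d t_i
       dw_dt = sqrt(2) * phi1,                 # d w_i / d t_i
       d2w_dt2 = sqrt(2) * phi2,
       d2n_dt2 = 4 * (phi1^2 + phi * phi2))
}

#' Occupations from unconstrained parameters
#'
#' Maps the unconstrained vector x to occupation numbers in (0, 2) whose sum
#' equals the electron count, by solving for the chemical potential mu in
#' `n_i = 2 Phi(x_i + mu)^2` with Phi the scaled error function
#' `(1 + erf)/2`.  The map keeps d sqrt(n)/dx bounded as n approaches 0,
#' which is what the square-root dependence of the Mueller functional needs.
#'
#' @param x numeric vector of length N.
#' @param n_electrons electron count N_e with 0 < N_e < 2 N.
#' @param tol tolerance on |sum(n) - N_e|.
#' @return list with `n` (occupations), `mu` (chemical potential).
#' @export
occupations_from_x <- function(x, n_electrons, tol = 1e-12) {
  N <- length(x)
  if (n_electrons <= 0 || n_electrons >= 2 * N) {
    stop("need 0 < n_electrons < 2N, got ", n_electrons, " with N = ", N)
  }
  trace_fun <- function(mu) sum(2 * .phi(x + mu)^2) - n_electrons
  # bracket: Phi is monotone increasing in mu
  lo <- -max(x) - 10
  hi <- -min(x) + 10
  while (trace_fun(lo) > 0) lo <- lo - 10
  while (trace_fun(hi) < 0) hi <- hi + 10
  root <- uniroot(trace_fun, c(lo, hi), tol = 1e-14)
  mu <- root$root
  # Newton polish on the strictly monotone trace function
  for (k in 1:50) {
    p <- .occ_pieces(x, mu)
    r <- sum(p$n) - n_electrons
    if (abs(r) < tol) break
    d <- sum(p$dn_dt)
    if (d <= 0) stop("occupation trace solve: vanishing derivative (all ",
                     "occupations saturated); diagnostics: mu=", mu,
                     " residual=", r)
    mu <- mu - r / d
  }
  p <- .occ_pieces(x, mu)
  if (abs(sum(p$n) - n_electrons) > 1e-9) {
    stop("occupation trace solve failed: residual ",
         format(sum(p$n) - n_electrons), " at mu = ", mu)
  }
  list(n = p$n, mu = mu)
}

#' Jacobian of the occupations including the implicit mu response
#'
#' Returns the matrix D with `D[i, j] = d n_i / d x_j`, where the chemical
#' potential's dependence on x is obtained by implicit differentiation of
#' the trace constraint.  Every column of D sums to zero (the trace is
#' conserved along any direction).
#'
#' @param x parameter vector.
#' @param mu chemical potential consistent with `x` (from
#'   [occupations_from_x()]).
#' @return N x N Jacobian matrix.
#' @export
occupation_jacobian <- function(x, mu) {
  p <- .occ_pieces(x, mu)
  if (abs(sum(p$n) - round(sum(p$n))) > 1e-6) {
    # consistency guard: mu must solve the trace equation for some integer N_e
    stop("stale state: (x, mu) pair does not satisfy a trace constraint")
  }
  d <- p$dn_dt
  mu_grad <- -d / sum(d)
  d * (diag(length(x)) + matrix(mu_grad, length(x), length(x), byrow = TRUE))
}

# derivative/curvature pieces of x -> (w = sqrt(n)) including mu response:
#   W[i,j]   = d w_i / d x_j
#   curvature: d2 w_i / dx_j dx_k = d2w_dt2_i T_ij T_ik + dw_dt_i mu_hess_jk
.w_map <- function(x, mu) {
  p <- .occ_pieces(x, mu)
  N <- length(x)
  d <- p$dn_dt
  mu_grad <- -d / sum(d)
  T <- diag(N) + matrix(mu_grad, N, N, byrow = TRUE)
  W <- p$dw_dt * T
  # second derivative of mu: sum_i d2n_i T_ij T_ik + sum_i dn_i mu_jk = 0
  mu_hess <- -crossprod(T, p$d2n_dt2 * T) / sum(d)
  list(pieces = p, T = T, W = W, mu_grad = mu_grad, mu_hess = mu_hess)
}

#' Orthogonal rotation from an antisymmetric generator
#'
#' `U = exp(X)` for antisymmetric X, computed with a dense matrix
#' exponential.  U is orthogonal with det +1.
#'
#' @param X antisymmetric N x N matrix.
#' @param tol antisymmetry tolerance.
#' @return orthogonal N x N matrix.
#' @export
rotation_from_X <- function(X, tol = 1e-12) {
  if (max(abs(X + t(X))) > tol * max(1, max(abs(X)))) {
    stop("generator X is not antisymmetric")
  }
  as.matrix(Matrix::expm(Matrix::Matrix(X)))
}

# pack/unpack the strictly upper triangle (row-major: (1,2),(1,3),...,(2,3),..)
.upper_pairs <- function(N) {
  if (N < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

.unpack_X <- function(xup, N, pairs = .upper_pairs(N)) {
  X <- matrix(0, N, N)
  X[pairs] <- xup
  X - t(X)
}

.pack_X <- function(X, pairs = .upper_pairs(nrow(X))) X[pairs]

#' Construct an RDM state
#'
#' Houses the current natural orbitals (columns of C over the AO basis),
#' the unconstrained occupation parameters x with their solved chemical
#' potential and occupations, and the (zero) rotation generator of the
#' current expansion point.
#'
#' @param C N x N coefficient matrix with `t(C) S C = I`.
#' @param x occupation parameter vector.
#' @param n_electrons electron count.
#' @param S AO overlap matrix (identity if omitted).
#' @return An object of class `rdmft_state`.
#' @export
rdm_state <- function(C, x, n_electrons, S = NULL) {
  N <- nrow(C)
  if (is.null(S)) S <- diag(N)
  occ <- occupations_from_x(x, n_electrons)
  ortho <- max(abs(crossprod(C, S %*% C) - diag(N)))
  if (ortho > 1e-8) stop("coefficients not S-orthonormal (residual ", ortho, ")")
  structure(
    list(coefficients = C, occ_params = x, chem_potential = occ$mu,
         occupations = occ$n, n_electrons = n_electrons, overlap = S,
         n_basis = N, n_rot = N * (N - 1L) / 2L,
         pairs = .upper_pairs(N)),
    class = "rdmft_state"
  )
}

#' Move the expansion point after an accepted step
#'
#' Applies the accepted step `(dx, dX)`: the orbitals are rotated by
#' `exp(X(dX))` (so the new expansion point again has X = 0), the occupation
#' parameters are shifted, and the chemical potential is re-solved.  Because
#' rotations do not commute, successive generators do not add; the expansion
#' point must be moved after every accepted step.  Orthonormality drift
#' beyond `1e-8` triggers symmetric re-orthonormalization (with a warning).
#'
#' @param state an `rdmft_state`.
#' @param dx occupation-parameter step (length N).
#' @param dX_up rotation step, strictly-upper-triangle vector (length
#'   N(N-1)/2), row-major pairs.
#' @return the recentered `rdmft_state`.
#' @export
recenter <- function(state, dx, dX_up) {
  N <- state$n_basis
  X <- .unpack_X(dX_up, N, state$pairs)
  U <- rotation_from_X(X)
  C_new <- state$coefficients %*% U
  S <- state$overlap
  drift <- max(abs(crossprod(C_new, S %*% C_new) - diag(N)))
  if (drift > 1e-8) {
    warning("orthonormality drift ", format(drift),
            "; re-orthonormalizing the orbitals")
    M <- crossprod(C_new, S %*% C_new)
    e <- eigen(.symmetrize(M), symmetric = TRUE)
    C_new <- C_new %*% (e$vectors %*% diag(1 / sqrt(e$values), N) %*% t(e$vectors))
  }
  rdm_state(C_new, state$occ_params + dx, state$n_electrons, S)
}

#' 1-RDM of a state in the AO basis
#'
#' `gamma = C diag(n) t(C)` (contravariant AO representation; its product
#' with S has trace N_e).
#'
#' @param state an `rdmft_state`.
#' @return N x N symmetric matrix.
#' @export
state_gamma <- function(state) {
  .symmetrize(state$coefficients %*% (state$occupations * t(state$coefficients)))
}

#' Jacobian and curvature of the x -> nu change of variables
#'
#' The redundant nu-space collects `w = sqrt(n)` and all N^2 entries of the
#' rotation U; energy derivatives are simplest there.  This returns the
#' Jacobian J = d nu / d x at the expansion point (X = 0, U = I) in
#' structured form (the w-block `W = dw/dx` is dense, the U-block maps the
#' upper-triangle generator entries to +-1 entries of U), together with the
#' curvature contraction operator
#' `g_nu -> sum_a g_nu[a] * d2 nu_a / dx dx` (a symmetric (N+M) x (N+M)
#' matrix, M = N(N-1)/2).
#'
#' @param state an `rdmft_state`.
#' @return An object of class `rdmft_numap` with fields `W`, `pairs`, `N`,
#'   `M`, and function `curvature_contraction(g_w, G_u)`.
#' @export
build_nu_map <- function(state) {
  N <- state$n_basis
  M <- state$n_rot
  pairs <- state$pairs
  wm <- .w_map(state$occ_params, state$chem_potential)
  p <- wm$pieces
  T <- wm$T
  mu_hess <- wm$mu_hess

  curvature_contraction <- function(g_w, G_u) {
    # w-part: sum_i g_w[i] [ d2w_dt2_i T_ij T_ik + dw_dt_i mu_hess ]
    occ_blk <- crossprod(T, (g_w * p$d2w_dt2) * T) +
      sum(g_w * p$dw_dt) * mu_hess
    # U-part: 1/2 tr(G' (A1 A2 + A2 A1)) for unit generators A1, A2;
    # with Gs = G + G' this reduces to delta-contracted entries of Gs.
    Gs <- G_u + t(G_u)
    a <- pairs[, 1]; b <- pairs[, 2]
    A <- matrix(a, M, M); B <- matrix(b, M, M)
    Cc <- t(A); D <- t(B)
    rot_blk <- 0.5 * (
      (B == Cc) * Gs[cbind(as.vector(A), as.vector(D))] -
      (B == D) * Gs[cbind(as.vector(A), as.vector(Cc))] -
      (A == Cc) * Gs[cbind(as.vector(B), as.vector(D))] +
      (A == D) * Gs[cbind(as.vector(B), as.vector(Cc))]
    )
    rot_blk <- matrix(rot_blk, M, M)
    out <- matrix(0, N + M, N + M)
    out[seq_len(N), seq_len(N)] <- occ_blk
    out[N + seq_len(M), N + seq_len(M)] <- rot_blk
    .symmetrize(out)
  }

  structure(
    list(W = wm$W, pairs = pairs, N = N, M = M,
         w = p$w, dw_dt = p$dw_dt, T = T,
         curvature_contraction = curvature_contraction),
    class = "rdmft_numap"
  )
}

#' Dense Jacobian of the x -> nu map
#'
#' Materializes J = d nu / d x as an (N + N^2) x (N + M) matrix (w rows
#' first, then vec(U) rows).  Mostly useful for tests; the solver uses the
#' structured form.
#'
#' @param map an `rdmft_numap`.
#' @return dense Jacobian matrix.
#' @export
nu_jacobian_dense <- function(map) {
  N <- map$N; M <- map$M
  J <- matrix(0, N + N * N, N + M)
  J[seq_len(N), seq_len(N)] <- map$W
  for (k in seq_len(M)) {
    a <- map$pairs[k, 1]; b <- map$pairs[k, 2]
    J[N + a + (b - 1) * N, N + k] <- 1
    J[N + b + (a - 1) * N, N + k] <- -1
  }
  J
}
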
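test_that("occupation map honours trace, bounds and monotonicity", {
  # symmetric input: every occupation must equal N_e / N
  o <- occupations_from_x(rep(0, 5), 5)
  expect_equal(o$n, rep(1, 5), tolerance = 1e-12)

  # saturating branch
  o2 <- occupations_from_x(c(10, 0), 2)
  expect_lt(abs(o2$n[1] - 2), 1e-6)

  set.seed(3)
  x <- rnorm(8)
  o3 <- occupations_from_x(x, 6)
  expect_lt(abs(sum(o3$n) - 6), 1e-12)
  expect_true(all(o3$n > 0 & o3$n < 2))
  # strictly increasing in each x_i (map through a common mu)
  expect_true(all(diff(2 * rdmft:::.phi(sort(x) + o3$mu)^2) > 0))

  expect_error(occupations_from_x(rep(0, 4), 8), "n_electrons")
})

test_that("occupation map is ensemble N-representable for 1000 random draws", {
  set.seed(7)
  for (k in 1:1000) {
    N <- sample(3:12, 1)
    ne <- 2 * sample.int(N - 1, 1)
    x <- runif(N, -50, 50)
    o <- occupations_from_x(x, ne)
    if (any(o$n < 0) || any(o$n > 2) || abs(sum(o$n) - ne) > 1e-10) {
      fail(sprintf("violation at draw %d", k))
    }
  }
  succeed()
})

test_that("d sqrt(n)/dx stays bounded over x in [-50, 50]", {
  x <- seq(-50, 50, length.out = 201)
  o <- occupations_from_x(c(x, 0), 2)
  wm <- rdmft:::.w_map(c(x, 0), o$mu)
  expect_true(all(is.finite(wm$W)))
  expect_lt(max(abs(wm$W)), 2)
})

test_that("occupation Jacobian conserves the trace and matches differences", {
  set.seed(11)
  x <- rnorm(7)
  o <- occupations_from_x(x, 6)
  D <- occupation_jacobian(x, o$mu)
  expect_lt(max(abs(colSums(D))), 1e-12)

  # permutation symmetry: equal x give constant diagonal / off-diagonal
  os <- occupations_from_x(rep(0.3, 5), 4)
  Ds <- occupation_jacobian(rep(0.3, 5), os$mu)
  expect_lt(max(abs(diag(Ds) - diag(Ds)[1])), 1e-12)
  off <- Ds[upper.tri(Ds)]
  expect_lt(max(abs(off - off[1])), 1e-12)

  # central finite differences through the implicit mu re-solve
  h <- 1e-6
  Dfd <- matrix(0, 7, 7)
  for (j in 1:7) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    Dfd[, j] <- (occupations_from_x(xp, 6)$n -
                 occupations_from_x(xm, 6)$n) / (2 * h)
  }
  expect_lt(max(abs(D - Dfd)) / max(abs(Dfd)), 1e-7)
})

test_that("rotation exponential is orthogonal and matches the closed forms", {
  expect_equal(rotation_from_X(matrix(0, 3, 3)), diag(3))

  th <- 0.3
  U <- rotation_from_X(rbind(c(0, th), c(-th, 0)))
  expect_equal(U, rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))),
               tolerance = 1e-12)

  set.seed(5)
  X <- matrix(rnorm(100), 10, 10)
  X <- X - t(X)
  U10 <- rotation_from_X(X)
  expect_lt(max(abs(crossprod(U10) - diag(10))), 1e-12)
  expect_equal(det(U10), 1, tolerance = 1e-10)
  # independent oracle: exponential via the eigendecomposition of iX
  ed <- eigen(1i * X)
  Uref <- Re(ed$vectors %*% diag(exp(-1i * ed$values)) %*% Conj(t(ed$vectors)))
  expect_lt(max(abs(U10 - Uref)), 1e-12)

  expect_error(rotation_from_X(matrix(1, 2, 2)), "antisymmetric")
})

test_that("recentering preserves orthonormality and is idempotent at zero", {
  fx <- fix_synth(6, 4, 2)
  st <- random_state(fx, 4, seed = 9)
  M <- st$n_rot

  st0 <- recenter(st, numeric(6), numeric(M))
  expect_equal(st0$coefficients, st$coefficients, tolerance = 1e-12)
  expect_equal(st0$occupations, st$occupations, tolerance = 1e-10)

  # chained random steps: orthonormality drift stays tiny
  set.seed(21)
  cur <- st
  for (k in 1:100) {
    cur <- recenter(cur, rnorm(6) * 0.05, rnorm(M) * 0.05)
  }
  res <- max(abs(crossprod(cur$coefficients, cur$overlap %*%
                             cur$coefficients) - diag(6)))
  expect_lt(res, 1e-9)

  # two successive small rotations agree with the combined one only to
  # second order (noncommutativity): assert closeness, not equality
  d1 <- rnorm(M) * 0.01
  d2 <- rnorm(M) * 0.01
  two <- recenter(recenter(st, numeric(6), d1), numeric(6), d2)
  one <- recenter(st, numeric(6), d1 + d2)
  dg <- max(abs(state_gamma(two) - state_gamma(one)))
  expect_lt(dg, 1e-3)
  expect_gt(dg, 0)
})

test_that("nu map Jacobian and curvature match the map's finite differences", {
  fx <- fix_synth(5, 4, 3)
  st <- random_state(fx, 4, seed = 4)
  N <- 5; M <- st$n_rot
  map <- build_nu_map(st)
  J <- nu_jacobian_dense(map)

  # U-block of unit rotation directions: +-1 generator pattern
  k <- 2L  # pair (1,3)
  expect_equal(st$pairs[k, ], c(row = 1L, col = 3L), ignore_attr = TRUE)
  col <- J[5 + seq_len(25), 5 + k]
  Ublk <- matrix(col, 5, 5)
  expect_equal(Ublk[1, 3], 1)
  expect_equal(Ublk[3, 1], -1)
  expect_equal(sum(abs(Ublk)), 2)

  # full Jacobian against finite differences of x -> nu
  nu_of <- function(z) {
    dx <- z[seq_len(N)]
    dX <- z[N + seq_len(M)]
    occ <- occupations_from_x(st$occ_params + dx, st$n_electrons)
    U <- rotation_from_X(rdmft:::.unpack_X(dX, N, st$pairs))
    c(sqrt(occ$n), as.vector(U))
  }
  h <- 1e-5
  Jfd <- matrix(0, N + N * N, N + M)
  for (j in seq_len(N + M)) {
    e <- numeric(N + M); e[j] <- h
    Jfd[, j] <- (nu_of(e) - nu_of(-e)) / (2 * h)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-7)

  # curvature contraction: zero covector gives the zero matrix, and the
  # contraction of a random covector matches FD of the map
  zero <- map$curvature_contraction(numeric(N), matrix(0, N, N))
  expect_equal(zero, matrix(0, N + M, N + M))

  set.seed(12)
  gv <- rnorm(N + N * N)
  Cfd <- matrix(0, N + M, N + M)
  f <- function(z) sum(gv * nu_of(z))
  for (a in seq_len(N + M)) for (b in seq_len(N + M)) {
    ea <- numeric(N + M); ea[a] <- h
    eb <- numeric(N + M); eb[b] <- h
    Cfd[a, b] <- (f(ea + eb) - f(ea - eb) - f(eb - ea) + f(-ea - eb)) /
      (4 * h^2)
  }
  Cexact <- map$curvature_contraction(gv[seq_len(N)],
                                      matrix(gv[-seq_len(N)], N, N)) +
    crossprod(J * 0, J)  # (J' 0 J) = 0; curvature only
  # FD of f includes the linear-map part too: subtract J' H_f J with H_f = 0
  # (f is linear in nu), so Cfd should equal the curvature contraction
  expect_lt(max(abs(Cexact - Cfd)) / max(1, max(abs(Cfd))), 1e-5)
})
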
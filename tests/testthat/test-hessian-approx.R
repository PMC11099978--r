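test_that("cheap + expensive reproduces the exact Hessian elementwise", {
  fx <- fix_synth(5, 4, 10)
  st <- random_state(fx, 4, seed = 1)
  cache <- transform_integrals(fx$ao, st$coefficients)
  He <- exact_hessian(st, cache)
  Hc <- cheap_hessian(st, cache)
  Hx <- expensive_hessian(st, cache)
  expect_lt(max(abs(Hc$full + Hx$full - He$full)), 1e-12)
  rem <- expensive_remainder(He, Hc)
  expect_lt(max(abs(rem$full - Hx$full)), 1e-12)
})

test_that("cheap NO block is exactly sparse on disjoint index pairs", {
  fx <- fix_synth(6, 4, 12)
  st <- random_state(fx, 4, seed = 2)
  cache <- transform_integrals(fx$ao, st$coefficients)
  Hc <- cheap_hessian(st, cache)
  pairs <- st$pairs
  M <- st$n_rot
  for (k in seq_len(M)) for (l in seq_len(M)) {
    if (length(intersect(pairs[k, ], pairs[l, ])) == 0) {
      expect_identical(Hc$no_block[k, l], 0)
    }
  }
  # and it is not sparse where indices overlap
  expect_gt(max(abs(Hc$no_block)), 0)
})

test_that("cheap Hessian equals the exact one for a one-electron system", {
  fx <- fix_synth(5, 4, 14)
  ao <- fx$ao
  ao$eri[] <- 0
  st <- rdm_state(fx$rhf$mo_coefficients, rnorm(5), 4)
  cache <- transform_integrals(ao, st$coefficients)
  expect_lt(max(abs(cheap_hessian(st, cache)$full -
                    exact_hessian(st, cache)$full)), 1e-12)
})

test_that("the occupation block is decently approximated at the first iterate", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf)
  st <- initialize_state(sys)
  cache <- transform_integrals(fw$ao, st$coefficients)
  He <- exact_hessian(st, cache)
  Hc <- cheap_hessian(st, cache)
  Hx <- expensive_remainder(He, Hc)
  # expensive occupation block small relative to the exact occupation block
  expect_lt(norm(Hx$on_block, "F") / norm(He$on_block, "F"), 0.5)
  # per-block error diagnostics are finite (Fig-9-style trace contract)
  err <- hessian_block_errors(He, Hc)
  expect_true(all(is.finite(err)))
  expect_named(err, c("on", "coupling", "no"))
})

test_that("BFGS update has its fixed point and satisfies the secant", {
  set.seed(3)
  B <- crossprod(matrix(rnorm(25), 5, 5))
  s <- rnorm(5)
  expect_equal(bfgs_update(B, s, as.vector(B %*% s)), B, tolerance = 1e-12)

  y <- rnorm(5)
  B2 <- bfgs_update(B, s, y)
  expect_lt(max(abs(B2 %*% s - y)), 1e-12)
  expect_lt(max(abs(B2 - t(B2))), 1e-12)

  # curvature floor: orthogonal pair is skipped
  s0 <- c(1, 0, 0, 0, 0); y0 <- c(0, 1, 0, 0, 0)
  Bskip <- bfgs_update(B, s0, y0 * 1e-20)
  expect_true(isTRUE(attr(Bskip, "skipped")))
})

test_that("BFGS recovers an SPD quadratic Hessian in n steps", {
  set.seed(4)
  n <- 4
  Q <- crossprod(matrix(rnorm(n * n), n, n)) + diag(n)
  b <- rnorm(n)
  B <- diag(n)
  x <- rnorm(n)
  for (k in 1:n) {
    g <- as.vector(Q %*% x - b)
    d <- -solve(B, g)
    alpha <- -sum(g * d) / sum(d * (Q %*% d))   # exact line search
    s <- alpha * d
    x <- x + s
    y <- as.vector(Q %*% s)
    B <- bfgs_update(B, s, y)
  }
  expect_lt(max(abs(B - Q)) / max(abs(Q)), 1e-8)
})

test_that("nu-space BFGS enforces the x-space secant on the expensive part", {
  fx <- fix_synth(5, 4, 16)
  st <- random_state(fx, 4, seed = 6)
  cache <- transform_integrals(fx$ao, st$coefficients)
  map <- build_nu_map(st)
  mem <- bfgs_memory(5)
  dim_x <- 5 + st$n_rot

  set.seed(9)
  s <- rnorm(dim_x) * 0.1
  y <- rnorm(dim_x)
  # genuine gradient differences carry no component along the occupation
  # gauge direction (a uniform shift of x is absorbed by mu); mimic that
  y[1:5] <- y[1:5] - mean(y[1:5])
  nu_bfgs_update(mem, s, y, map)
  expect_equal(mem$n_updates, 1L)
  expect_lt(max(abs(mem$B - t(mem$B))), 1e-12)

  # the assembled expensive model reproduces y on s
  hc <- cheap_hessian(st, cache)
  Bx <- assemble_approx_hessian(hc, mem, map, A = 1)
  expect_lt(max(abs((Bx - hc$full) %*% s - y)) / max(abs(y)), 1e-8)

  # zero step leaves the memory unchanged; reset clears it
  Bold <- mem$B
  nu_bfgs_update(mem, numeric(dim_x), y, map)
  expect_identical(mem$B, Bold)
  bfgs_reset(mem)
  expect_true(all(mem$B == 0))
  expect_equal(mem$n_updates, 0L)
})

test_that("repeated secant pairs from a quadratic model shrink the error", {
  # synthetic quadratic in nu-space: secant pairs generated from the true
  # expensive Hessian must drive the assembled model towards it
  fx <- fix_synth(4, 4, 18)
  st <- random_state(fx, 4, seed = 7)
  cache <- transform_integrals(fx$ao, st$coefficients)
  map <- build_nu_map(st)
  Hx_exp <- expensive_hessian(st, cache)$full
  hc <- cheap_hessian(st, cache)
  mem <- bfgs_memory(4)
  dim_x <- 4 + st$n_rot
  err <- function() {
    Bx <- assemble_approx_hessian(hc, mem, map, A = 1)
    norm((Bx - hc$full) - Hx_exp, "F") / norm(Hx_exp, "F")
  }
  e0 <- err()
  set.seed(10)
  errs <- numeric(30)
  for (k in 1:30) {
    s <- rnorm(dim_x)
    y <- as.vector(Hx_exp %*% s)
    nu_bfgs_update(mem, s, y, map)
    errs[k] <- err()
  }
  expect_lt(errs[30], e0)
  expect_lt(errs[30], errs[5])
})

test_that("chain-rule identity: exact expensive nu-Hessian reproduces H_exp", {
  fx <- fix_synth(4, 4, 22)
  st <- random_state(fx, 4, seed = 8)
  cache <- transform_integrals(fx$ao, st$coefficients)
  map <- build_nu_map(st)
  nt <- rdmft:::.nu_terms(cache, st$occupations,
                          separable_functional("muller"),
                          part = "expensive")
  mem <- bfgs_memory(4)
  mem$B[seq_len(4), seq_len(4)] <- nt$Hww
  mem$B[seq_len(4), 4 + seq_len(16)] <- nt$HwU
  mem$B[4 + seq_len(16), seq_len(4)] <- t(nt$HwU)
  mem$B[4 + seq_len(16), 4 + seq_len(16)] <- nt$HUU

  hc <- cheap_hessian(st, cache)
  Bx <- assemble_approx_hessian(hc, mem, map, A = 1)
  He <- exact_hessian(st, cache)
  expect_lt(max(abs(Bx - He$full)) / max(abs(He$full)), 1e-8)

  # A = 0 gates the correction off entirely
  expect_identical(assemble_approx_hessian(hc, mem, map, A = 0), hc$full)
})

test_that("prefactor has the required limits and monotonicity", {
  expect_equal(prefactor(numeric(5)), 1)
  expect_equal(prefactor(numeric(0)), 1)
  expect_lt(prefactor(c(0.1, 0), tau = 1e-3), 1e-6)
  v <- vapply(seq(0, 0.01, length.out = 50),
              function(s) prefactor(c(s, 0), tau = 1e-3), 1.0)
  expect_true(all(diff(v) <= 0))
  expect_error(prefactor(1, tau = -1), "positive")
})

test_that("structural cost split: coupling entries are asymptotically few", {
  for (N in c(10L, 20L, 40L)) {
    M <- N * (N - 1L) / 2L
    expect_lt(N * M / M^2, 3 / N)   # coupling share vanishes like 1/N
  }
})
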
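test_that("Fermi-Dirac initialization hits the trace and the HF limit", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf)

  for (beta in c(1, 10, 50)) {
    st <- initialize_state(sys, beta = beta)
    expect_lt(abs(sum(st$occupations) - 10), 1e-10)
  }

  # large-beta limit: idempotent HF occupations (2 for the 5 lowest levels)
  st_cold <- initialize_state(sys, beta = 1e4)
  ord <- order(fw$rhf$orbital_energies)
  expect_equal(st_cold$occupations[ord][1:5], rep(2, 5), tolerance = 1e-8)
  expect_equal(st_cold$occupations[ord][6:7], rep(0, 2), tolerance = 1e-8)

  # x -> n -> x round trip is stable
  st <- initialize_state(sys, beta = 10)
  n1 <- st$occupations
  x2 <- rdmft:::.phi_inv(sqrt(n1 / 2)) - st$chem_potential
  o2 <- occupations_from_x(x2 + st$chem_potential, 10)
  expect_lt(max(abs(o2$n - n1)), 1e-10)
})

test_that("1-step exact Hessian converges H2 quickly to the grid optimum", {
  fx <- fix_h2_sto3g()
  sys <- rdmft_system(fx$ao, fx$rhf, tag = "h2-grid")
  res <- run_one_step(sys, rdmft_config("one_step", "exact"))
  expect_true(res$converged)
  expect_lt(res$grad_norm, 1e-6)
  expect_lte(res$n_iter, 15)

  # brute-force oracle over the 2-parameter energy surface (n1, theta):
  # occupations (n1, 2 - n1), orbitals C0 rotated by theta
  cache0 <- transform_integrals(fx$ao, fx$rhf$mo_coefficients)
  e_surface <- function(n1, th) {
    U <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    cc <- transform_integrals(fx$ao, fx$rhf$mo_coefficients %*% U)
    rdmft_energy(cc, c(n1, 2 - n1))
  }
  grid_n <- seq(1.90, 2 - 1e-12, length.out = 60)
  grid_t <- seq(-0.3, 0.3, length.out = 31)
  e_grid <- min(vapply(grid_n, function(n1) {
    min(vapply(grid_t, function(th) e_surface(n1, th), 1.0))
  }, 1.0))
  best <- optim(c(1.96, 0), function(p) e_surface(min(max(p[1], 1e-12),
                                                      2 - 1e-12), p[2]),
                method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))
  e_opt <- min(e_grid, best$value)
  expect_lt(abs(res$energy - e_opt), 1e-8)
})

test_that("zeroing the coupling block reaches the same minimum", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf)
  # a tight micro tolerance isolates the minimum-location comparison from
  # termination scatter along the flat occupation-saturation valley
  res_on <- run_one_step(sys, rdmft_config("one_step", "exact",
                                           coupling = "on", gtol = 3e-8))
  res_off <- run_one_step(sys, rdmft_config("one_step", "exact",
                                            coupling = "off", gtol = 3e-8))
  expect_true(res_on$converged && res_off$converged)
  expect_lt(abs(res_on$energy - res_off$energy), 1e-8)
})

test_that("the exact-Hessian minimum has no negative eigenvalues", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf)
  res <- run_one_step(sys, rdmft_config("one_step", "exact"))
  cache <- transform_integrals(fw$ao, res$state$coefficients)
  H <- exact_hessian(res$state, cache)
  cnt <- count_negative_eigenvalues(H, tol = 1e-8)
  expect_equal(cnt$n_total, 0L)
  expect_equal(cnt$n_on, 0L)
  expect_equal(cnt$n_no, 0L)
})

test_that("all Hessian modes drive the same driver to the same minimum", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf, tag = "h2o-modes")
  energies <- c()
  for (mode in c("exact", "cheap", "cheap+bfgs_nu")) {
    res <- run_one_step(sys, rdmft_config("one_step", mode))
    expect_true(res$converged)
    energies[mode] <- res$energy
  }
  expect_lt(diff(range(energies)), 1e-7)
})

test_that("2-step agrees with 1-step but needs more iterations", {
  fw <- fix_h2o_sto3g()
  sys <- rdmft_system(fw$ao, fw$rhf)
  res1 <- run_one_step(sys, rdmft_config("one_step", "exact"))
  res2 <- run_two_step(sys, rdmft_config("two_step", "exact"))
  expect_true(res2$converged)
  expect_lt(abs(res1$energy - res2$energy), 1e-7)
  expect_gt(res2$n_iter, res1$n_iter)
  expect_gte(res2$n_macro, 2L)
  expect_true(all(c(1L, 2L) %in% res2$trace$phase))
})

test_that("reference energies update monotonically downward", {
  tag <- paste0("ref-test-", as.integer(stats::runif(1, 1, 1e8)))
  e0 <- reference_energy(tag)
  expect_true(is.na(e0))
  expect_true(isTRUE(attr(e0, "unavailable")))
  rdmft:::.update_reference(tag, -1.0)
  expect_equal(reference_energy(tag), -1.0)
  rdmft:::.update_reference(tag, -0.5)    # higher value must not replace
  expect_equal(reference_energy(tag), -1.0)
  rdmft:::.update_reference(tag, -1.2)
  expect_equal(reference_energy(tag), -1.2)
})

test_that("macro restarts reset the quasi-Newton memory", {
  mem <- bfgs_memory(3)
  mem$B[1, 1] <- 5
  mem$n_updates <- 4L
  bfgs_reset(mem)
  expect_true(all(mem$B == 0))
  expect_equal(mem$n_updates, 0L)
})
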
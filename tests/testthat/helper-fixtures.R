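# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_h2_sto3g <- function() fixture("h2_sto3g", function() {
  ao <- compute_ao_integrals(builtin_molecule("H2"), "sto-3g")
  list(ao = ao, rhf = run_rhf(ao))
})

fix_h2o_sto3g <- function() fixture("h2o_sto3g", function() {
  ao <- compute_ao_integrals(builtin_molecule("H2O"), "sto-3g")
  list(ao = ao, rhf = run_rhf(ao))
})

fix_synth <- function(n, ne, seed) {
  fixture(sprintf("synth_%d_%d_%d", n, ne, seed),
          function() synthetic_integrals(n, ne, seed = seed))
}

# random valid state on a fixture system
random_state <- function(fx, n_electrons, seed = 1, scale = 0.5) {
  set.seed(seed)
  N <- fx$ao$n_basis
  x <- rnorm(N) * scale
  # random orthogonal rotation of the reference orbitals
  X <- matrix(rnorm(N * N), N, N) * scale / N
  X <- X - t(X)
  C <- fx$rhf$mo_coefficients %*% rotation_from_X(X)
  rdm_state(C, x, n_electrons, S = fx$ao$overlap)
}

write_xyz <- function(lines) {
  f <- tempfile(fileext = ".xyz")
  writeLines(lines, f)
  f
}
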
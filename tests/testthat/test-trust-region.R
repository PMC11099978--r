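test_that("subproblem returns the Newton step when it fits", {
  r <- solve_subproblem(c(1, 0), diag(2), 10)
  expect_equal(r$step, c(-1, 0), tolerance = 1e-12)
  expect_false(r$on_boundary)
  expect_equal(r$predicted_decrease, 0.5, tolerance = 1e-12)
})

test_that("subproblem exploits negative curvature in the hard case", {
  r <- solve_subproblem(c(0, 0), diag(c(1, -1)), 1)
  expect_equal(sqrt(sum(r$step^2)), 1, tolerance = 1e-10)
  expect_gt(abs(r$step[2]), 0.99)      # along the negative-curvature axis
  expect_equal(r$predicted_decrease, 0.5, tolerance = 1e-10)
})

test_that("subproblem beats random search on indefinite 5x5 models", {
  set.seed(13)
  for (case in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    H <- (A + t(A)) / 2            # indefinite with high probability
    g <- rnorm(5)
    radius <- runif(1, 0.5, 2)
    r <- solve_subproblem(g, H, radius)
    expect_lte(sqrt(sum(r$step^2)), radius * (1 + 1e-8))
    model <- function(p) sum(g * p) + 0.5 * sum(p * (H %*% p))
    m_star <- model(r$step)
    pts <- matrix(rnorm(5 * 1e5), 5)
    pts <- pts * rep(runif(1e5)^(1 / 5) * radius /
                       sqrt(colSums(pts^2)), each = 5)
    m_rand <- min(g %*% pts + 0.5 * colSums(pts * (H %*% pts)))
    expect_lte(m_star, m_rand + 1e-8)
  }
})

test_that("steihaug alternative stays feasible and decreases the model", {
  set.seed(14)
  A <- matrix(rnorm(25), 5, 5)
  H <- (A + t(A)) / 2
  g <- rnorm(5)
  r <- solve_subproblem(g, H, 0.7, method = "cg-steihaug")
  expect_lte(sqrt(sum(r$step^2)), 0.7 * (1 + 1e-8))
  expect_gte(r$predicted_decrease, 0)
})

# generic smooth-function wrapper for the callback interface
quad_objective <- function(x0, f, g, h) {
  env <- new.env()
  env$x <- x0
  list(energy = function(p) f(env$x + p),
       gradient = function() g(env$x),
       hessian = function() h(env$x),
       accept = function(p) env$x <- env$x + p,
       env = env)
}

test_that("minimize solves a convex quadratic in a few evaluations", {
  Q <- rbind(c(2, 0.3), c(0.3, 1))
  b <- c(0.2, -0.4)
  ob <- quad_objective(c(0.1, 0.1),
                       function(z) 0.5 * sum(z * (Q %*% z)) - sum(b * z),
                       function(z) as.vector(Q %*% z - b),
                       function(z) Q)
  res <- tr_minimize(ob, 2, trust_region_config(gtol = 1e-10), e0 = NULL)
  expect_true(res$converged)
  expect_lte(res$n_iter, 3)
  expect_lt(res$grad_norm, 1e-10)
})

test_that("minimize solves Rosenbrock with monotone accepted energies", {
  f <- function(z) (1 - z[1])^2 + 100 * (z[2] - z[1]^2)^2
  g <- function(z) c(-2 * (1 - z[1]) - 400 * z[1] * (z[2] - z[1]^2),
                     200 * (z[2] - z[1]^2))
  h <- function(z) rbind(c(2 - 400 * (z[2] - 3 * z[1]^2), -400 * z[1]),
                         c(-400 * z[1], 200))
  ob <- quad_objective(c(-1.2, 1), f, g, h)
  res <- tr_minimize(ob, 2, trust_region_config(gtol = 1e-9, max_iter = 200),
                     e0 = NULL)
  expect_true(res$converged)
  expect_equal(ob$env$x, c(1, 1), tolerance = 1e-6)
  acc <- res$trace$energy[res$trace$accepted]
  expect_true(all(diff(acc) <= 0))
})

test_that("the state moves only on accepted steps", {
  calls <- new.env()
  calls$x <- c(1, 1, 1)
  calls$n_accept <- 0L
  # deliberately poor model (wrong curvature sign) to provoke rejections
  f <- function(z) sum(abs(z)^1.2) * 5
  ob <- list(
    energy = function(p) f(calls$x + p),
    gradient = function() rep(1, 3),
    hessian = function() -diag(3),
    accept = function(p) {
      calls$x <- calls$x + p
      calls$n_accept <- calls$n_accept + 1L
    })
  res <- tr_minimize(ob, 3, trust_region_config(max_iter = 25),
                     e0 = f(calls$x))
  expect_equal(calls$n_accept, sum(res$trace$accepted))
  expect_equal(calls$n_accept, res$n_accepted)
  # the final state is consistent with the reported energy
  expect_equal(f(calls$x), res$energy, tolerance = 1e-12)
  # accepted steps never increased the objective
  acc <- res$trace$energy[res$trace$accepted]
  if (length(acc) > 1) expect_true(all(diff(acc) <= 0))
})

test_that("a NaN objective aborts gracefully with a partial trace", {
  count <- new.env(); count$k <- 0
  ob <- list(
    energy = function(p) {
      count$k <- count$k + 1
      if (count$k > 2) NaN else sum((c(1, 1) + p)^2)
    },
    gradient = function() c(2, 2),
    hessian = function() 2 * diag(2),
    accept = function(p) invisible(NULL))
  res <- tr_minimize(ob, 2, trust_region_config(), e0 = 2)
  expect_false(res$converged)
  expect_true(res$status %in% c("non_finite_objective", "radius_underflow"))
  expect_true(is.data.frame(res$trace))
})
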
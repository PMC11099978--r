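# Trust-region (quasi-)Newton optimizer robust to indefinite Hessians.
# The subproblem  min_p g'p + p'Hp/2  s.t. ||p|| <= radius  is solved
# exactly through the eigendecomposition of H (More-Sorensen secular
# equation, hard case included); a truncated-CG (Steihaug) alternative is
# available as the economical option.

#' Trust-region configuration
#'
#' @param initial_radius initial trust radius.
#' @param eta_accept minimal reduction ratio for step acceptance (in (0,1)).
#'   The default 0.25 coincides with the shrink threshold (the strict
#'   acceptance convention of Coleman-Li-type solvers): steps whose actual
#'   reduction falls well short of the model prediction are rejected rather
#'   than half-heartedly accepted, which keeps the trust radius healthy in
#'   the very flat valleys that occur when occupations saturate towards 0
#'   or 2.
#' @param shrink,grow radius update factors (shrink < 1 < grow).
#' @param shrink_threshold,grow_threshold reduction-ratio thresholds.
#' @param max_iter maximum number of objective evaluations.
#' @param gtol gradient 2-norm termination threshold.
#' @param min_radius radius underflow threshold (non-convergence signal).
#' @param subproblem `"eigen-exact"` or `"cg-steihaug"`.
#' @return list of class `rdmft_tr_config`.
#' @export
trust_region_config <- function(initial_radius = 1.0, eta_accept = 0.25,
                                shrink = 0.25, grow = 2.0,
                                shrink_threshold = 0.25,
                                grow_threshold = 0.75,
                                max_iter = 500L, gtol = 1e-6,
                                min_radius = 1e-12,
                                subproblem = c("eigen-exact", "cg-steihaug")) {
  stopifnot(eta_accept > 0, eta_accept < 1, shrink < 1, grow > 1,
            initial_radius > 0, gtol > 0)
  structure(list(initial_radius = initial_radius, eta_accept = eta_accept,
                 shrink = shrink, grow = grow,
                 shrink_threshold = shrink_threshold,
                 grow_threshold = grow_threshold,
                 max_iter = as.integer(max_iter), gtol = gtol,
                 min_radius = min_radius,
                 subproblem = match.arg(subproblem)),
            class = "rdmft_tr_config")
}

#' Exact trust-region subproblem solution
#'
#' Minimizes the quadratic model `g'p + p'Hp/2` over `||p|| <= radius` via
#' the eigendecomposition of H: the Newton step when H is positive definite
#' and interior, otherwise the boundary solution of the secular equation,
#' with the hard case (gradient orthogonal to the most negative eigenspace)
#' handled by adding an eigenvector component.
#'
#' @param g gradient vector.
#' @param H symmetric matrix.
#' @param radius trust radius (> 0).
#' @param method `"eigen-exact"` (default) or `"cg-steihaug"`.
#' @return list `step`, `predicted_decrease` (>= 0), `on_boundary`.
#' @export
solve_subproblem <- function(g, H, radius, method = "eigen-exact") {
  if (!all(is.finite(g)) || !all(is.finite(H))) {
    stop("non-finite model inputs to the trust-region subproblem")
  }
  if (radius <= 0) stop("radius must be positive")
  if (method == "cg-steihaug") return(.steihaug(g, H, radius))
  n <- length(g)
  ed <- eigen(.symmetrize(H), symmetric = TRUE)
  lam <- ed$values
  gq <- as.vector(crossprod(ed$vectors, g))
  lam_min <- lam[n]

  pnorm_of <- function(shift) {
    d <- lam + shift
    sqrt(sum((gq / d)^2))
  }
  step_of <- function(shift) {
    d <- lam + shift
    as.vector(ed$vectors %*% (-gq / d))
  }

  if (lam_min > 0 && pnorm_of(0) <= radius) {
    p <- step_of(0)
    pred <- -(sum(g * p) + 0.5 * sum(p * (H %*% p)))
    return(list(step = p, predicted_decrease = max(pred, 0),
                on_boundary = FALSE))
  }

  # boundary solution: find shift > max(0, -lam_min) with ||p(shift)|| = radius
  shift_lo <- max(0, -lam_min)
  min_space <- which(abs(lam - lam_min) < 1e-12 * max(1, abs(lam_min)))
  g_in_min <- sqrt(sum(gq[min_space]^2))
  hard <- FALSE
  if (g_in_min < 1e-12 * max(1, sqrt(sum(gq^2)))) {
    # potential hard case: solution at shift = -lam_min with the minimal
    # eigenspace excluded, padded to the boundary by an eigenvector
    gq_r <- gq
    gq_r[min_space] <- 0
    d <- lam + shift_lo
    d[min_space] <- 1
    p_r <- -gq_r / d
    if (sqrt(sum(p_r^2)) <= radius) {
      hard <- TRUE
      tau <- sqrt(max(radius^2 - sum(p_r^2), 0))
      pq <- p_r
      pq[min_space[1]] <- pq[min_space[1]] + tau
      p <- as.vector(ed$vectors %*% pq)
    }
  }
  if (!hard) {
    # safeguarded Newton on 1/||p(shift)|| - 1/radius (monotone)
    lo <- shift_lo
    hi <- shift_lo + max(1, abs(lam_min)) + sqrt(sum(gq^2)) / radius
    while (pnorm_of(hi) > radius) hi <- shift_lo + 2 * (hi - shift_lo)
    shift <- 0.5 * (lo + hi)
    if (lo == 0 && pnorm_of(1e-300) <= 1e300) {
      # ensure starting point strictly inside the bracket
      shift <- max(shift, lo + 1e-14 * max(1, abs(lam_min)))
    }
    for (it in 1:100) {
      d <- lam + shift
      if (any(d <= 0)) {
        lo <- shift
        shift <- 0.5 * (lo + hi)
        next
      }
      pn <- pnorm_of(shift)
      if (abs(pn - radius) < 1e-11 * radius) break
      if (pn > radius) lo <- shift else hi <- shift
      # Newton step on phi(shift) = 1/pn - 1/radius
      dpn2 <- -2 * sum(gq^2 / d^3)          # d ||p||^2 / d shift
      dphi <- -0.5 * dpn2 / pn^3
      newton <- shift - (1 / pn - 1 / radius) / dphi
      shift <- if (newton > lo && newton < hi) newton else 0.5 * (lo + hi)
    }
    p <- step_of(shift)
    # scale exactly onto the boundary to guard vs leftover mismatch
    p <- p * (radius / sqrt(sum(p^2)))
  }
  pred <- -(sum(g * p) + 0.5 * sum(p * (H %*% p)))
  list(step = p, predicted_decrease = max(pred, 0), on_boundary = TRUE)
}

# Steihaug truncated conjugate gradient (economical alternative)
.steihaug <- function(g, H, radius, tol = 1e-10) {
  n <- length(g)
  p <- numeric(n)
  r <- -g
  d <- r
  if (sqrt(sum(r^2)) < tol) {
    return(list(step = p, predicted_decrease = 0, on_boundary = FALSE))
  }
  boundary_step <- function(p, d) {
    # tau >= 0 with ||p + tau d|| = radius
    a <- sum(d^2); b <- 2 * sum(p * d); cc <- sum(p^2) - radius^2
    tau <- (-b + sqrt(max(b^2 - 4 * a * cc, 0))) / (2 * a)
    p + tau * d
  }
  for (k in seq_len(2L * n)) {
    Hd <- as.vector(H %*% d)
    dHd <- sum(d * Hd)
    if (dHd <= 0) {
      p <- boundary_step(p, d)
      break
    }
    alpha <- sum(r^2) / dHd
    p_next <- p + alpha * d
    if (sqrt(sum(p_next^2)) >= radius) {
      p <- boundary_step(p, d)
      break
    }
    r_next <- r - alpha * Hd
    if (sqrt(sum(r_next^2)) < tol * max(1, sqrt(sum(g^2)))) {
      p <- p_next
      break
    }
    beta <- sum(r_next^2) / sum(r^2)
    d <- r_next + beta * d
    p <- p_next
    r <- r_next
  }
  pred <- -(sum(g * p) + 0.5 * sum(p * (H %*% p)))
  list(step = p, predicted_decrease = max(pred, 0),
       on_boundary = abs(sqrt(sum(p^2)) - radius) < 1e-8 * radius)
}

#' Trust-region minimization of a provided objective
#'
#' The objective is a list of callbacks operating on a local chart around a
#' moving expansion point: `energy(p)` evaluates at displacement p,
#' `gradient()` / `hessian()` give derivatives at the current expansion
#' point, `accept(p)` moves the expansion point (after which displacements
#' are measured from the new point), and optional `on_reject()`.  Every call
#' to `energy()` counts as one iteration (the paper-style accounting where
#' rejected trust-region steps are reported too).
#'
#' @param objective callback list (see Details).
#' @param dim problem dimension.
#' @param config an `rdmft_tr_config`.
#' @param e0 objective value at the starting expansion point (computed via
#'   `energy(0)` if omitted, which then also counts as an evaluation).
#' @param trace_extra optional function returning a named list appended to
#'   each iteration record.
#' @return list `converged`, `energy`, `grad_norm`, `n_iter` (objective
#'   evaluations), `n_accepted`, `trace` (data.frame), `status`.
#' @export
tr_minimize <- function(objective, dim, config = trust_region_config(),
                        e0 = NULL, trace_extra = NULL) {
  radius <- config$initial_radius
  records <- list()
  n_eval <- 0L
  n_acc <- 0L
  if (is.null(e0)) {
    e0 <- objective$energy(numeric(dim))
    n_eval <- n_eval + 1L
  }
  e_cur <- e0
  status <- "max_iter"
  g <- objective$gradient()
  gnorm <- sqrt(sum(g^2))
  H <- NULL

  push <- function(acc, pred, act, gn) {
    rec <- list(iter = n_eval, energy = e_cur, grad_norm = gn,
                radius = radius, accepted = acc,
                predicted = pred, actual = act)
    if (!is.null(trace_extra)) rec <- c(rec, trace_extra())
    records[[length(records) + 1L]] <<- rec
  }

  if (gnorm < config$gtol) {
    status <- "gtol"
  } else {
    while (n_eval < config$max_iter) {
      if (is.null(H)) H <- objective$hessian()
      sub <- tryCatch(
        solve_subproblem(g, H, radius, method = config$subproblem),
        error = function(e) NULL)
      if (is.null(sub)) {
        status <- "numerical_error"
        break
      }
      p <- sub$step
      e_trial <- objective$energy(p)
      n_eval <- n_eval + 1L
      if (!is.finite(e_trial)) {
        status <- "non_finite_objective"
        push(FALSE, sub$predicted_decrease, NA_real_, gnorm)
        break
      }
      actual <- e_cur - e_trial
      rho <- if (sub$predicted_decrease > 0) {
        actual / sub$predicted_decrease
      } else {
        # zero predicted decrease with nonzero gradient: treat as failure
        -Inf
      }
      accept <- is.finite(rho) && rho >= config$eta_accept && actual > 0
      if (accept) {
        objective$accept(p)
        e_cur <- e_trial
        n_acc <- n_acc + 1L
        g <- objective$gradient()
        gnorm <- sqrt(sum(g^2))
        H <- NULL
      } else if (!is.null(objective$on_reject)) {
        objective$on_reject()
      }
      push(accept, sub$predicted_decrease, actual, gnorm)
      # radius update
      if (!is.finite(rho) || rho < config$shrink_threshold) {
        radius <- radius * config$shrink
      } else if (rho > config$grow_threshold && sub$on_boundary) {
        radius <- radius * config$grow
      }
      if (gnorm < config$gtol) {
        status <- "gtol"
        break
      }
      if (radius < config$min_radius) {
        status <- "radius_underflow"
        break
      }
    }
  }
  trace <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  list(converged = identical(status, "gtol"), energy = e_cur,
       grad_norm = gnorm, n_iter = n_eval, n_accepted = n_acc,
       trace = trace, status = status)
}
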
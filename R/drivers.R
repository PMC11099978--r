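# 1-step and 2-step self-consistent drivers: initialization from a
# Hartree-Fock reference with Fermi-Dirac-like occupations, the trust-region
# micro loop over (x, X^up) (jointly, or alternating occupation / orbital
# phases), and the macro loop whose restart resets the quasi-Newton memory.

#' Bundle integrals, reference and functional into a system
#'
#' @param ao an `rdmft_ao`.
#' @param rhf an `rdmft_rhf` (computed from `ao` if omitted).
#' @param functional an `rdmft_functional`.
#' @param n_electrons electron count (defaults to the molecule's).
#' @param tag optional name used by the reference-energy registry.
#' @return list of class `rdmft_system`.
#' @export
rdmft_system <- function(ao, rhf = NULL,
                         functional = separable_functional("muller"),
                         n_electrons = NULL, tag = NULL) {
  if (is.null(n_electrons)) {
    if (is.null(ao$molecule)) stop("n_electrons required for synthetic integrals")
    n_electrons <- ao$molecule$n_electrons
  }
  if (is.null(rhf)) rhf <- run_rhf(ao, n_electrons)
  structure(list(ao = ao, rhf = rhf, functional = functional,
                 n_electrons = n_electrons, tag = tag),
            class = "rdmft_system")
}

#' Run configuration
#'
#' @param scheme `"one_step"` (joint occupation/orbital updates) or
#'   `"two_step"` (alternating phases).
#' @param hessian_mode `"exact"`, `"cheap"`, or `"cheap+bfgs_nu"`.
#' @param coupling include the occupation-orbital coupling block of the
#'   Hessian (`"on"`) or zero it (`"off"`).
#' @param gtol micro termination: gradient 2-norm threshold.
#' @param etol macro termination: |energy change| threshold (Hartree).
#' @param beta inverse temperature (Hartree^-1) of the Fermi-Dirac-like
#'   initial occupation distribution.
#' @param tau decay scale of the quasi-Newton gating prefactor.
#' @param macro_max,micro_max iteration caps.
#' @param tr trust-region configuration (radius schedule etc.).
#' @return list of class `rdmft_run_config`.
#' @export
rdmft_config <- function(scheme = c("one_step", "two_step"),
                         hessian_mode = c("exact", "cheap", "cheap+bfgs_nu"),
                         coupling = c("on", "off"),
                         gtol = 1e-6, etol = 1e-8, beta = 10, tau = 1e-3,
                         macro_max = 50L, micro_max = 500L,
                         tr = trust_region_config()) {
  stopifnot(gtol > 0, etol > 0, beta > 0, tau > 0)
  structure(list(scheme = match.arg(scheme),
                 hessian_mode = match.arg(hessian_mode),
                 coupling = match.arg(coupling),
                 gtol = gtol, etol = etol, beta = beta, tau = tau,
                 macro_max = as.integer(macro_max),
                 micro_max = as.integer(micro_max), tr = tr),
            class = "rdmft_run_config")
}

#' Initial state: Hartree-Fock orbitals, Fermi-Dirac-like occupations
#'
#' Occupations are set to `n_i = 2 / (1 + exp(beta (eps_i - mu0)))` with mu0
#' solved for the trace, then inverted through the occupation map to obtain
#' the unconstrained parameters x (chemical potential folded into x, so the
#' state's own mu re-solves to ~0).
#'
#' @param system an `rdmft_system`.
#' @param beta inverse temperature in Hartree^-1.
#' @return an `rdmft_state`.
#' @export
initialize_state <- function(system, beta = 10) {
  eps <- system$rhf$orbital_energies
  ne <- system$n_electrons
  fd <- function(mu0) sum(2 / (1 + exp(beta * (eps - mu0)))) - ne
  lo <- min(eps) - 10
  hi <- max(eps) + 10
  mu0 <- uniroot(fd, c(lo, hi), tol = 1e-14)$root
  n <- 2 / (1 + exp(beta * (eps - mu0)))
  # keep the inverse map finite; the trace re-solve absorbs the clipping
  n <- pmin(pmax(n, 1e-15), 2 - 1e-15)
  x <- .phi_inv(sqrt(n / 2))
  rdm_state(system$rhf$mo_coefficients, x, ne, S = system$ao$overlap)
}

# ---------------------------------------------------------------------------
# objective factory: local-chart callbacks for tr_minimize, with optional
# subspace masking (two-step phases) and the three Hessian modes.
.make_objective <- function(system, state0, config, memory = NULL,
                            subspace = NULL) {
  env <- new.env(parent = emptyenv())
  env$state <- state0
  env$cache <- transform_integrals(system$ao, state0$coefficients)
  env$grad <- NULL
  env$h_cheap <- NULL
  env$map <- NULL
  env$A <- 1
  env$trial <- NULL
  fun <- system$functional
  N <- state0$n_basis
  M <- state0$n_rot
  full_dim <- N + M
  if (is.null(subspace)) subspace <- seq_len(full_dim)
  use_bfgs <- identical(config$hessian_mode, "cheap+bfgs_nu")

  expand <- function(p) {
    z <- numeric(full_dim)
    z[subspace] <- p
    z
  }

  refresh <- function() {
    env$grad <- rdmft_gradient(env$state, env$cache, fun)
    env$map <- build_nu_map(env$state)
    if (use_bfgs) env$h_cheap <- cheap_hessian(env$state, env$cache, fun)
  }
  refresh()

  trial_state <- function(z) {
    dx <- z[seq_len(N)]
    dX <- z[N + seq_len(M)]
    recenter(env$state, dx, dX)
  }

  energy <- function(p) {
    z <- expand(p)
    if (max(abs(z)) == 0) {
      return(rdmft_energy(env$cache, env$state$occupations, fun))
    }
    st <- trial_state(z)
    cache <- transform_integrals(system$ao, st$coefficients)
    e <- rdmft_energy(cache, st$occupations, fun)
    env$trial <- list(p = p, state = st, cache = cache)
    e
  }

  gradient <- function() env$grad$vec[subspace]

  hessian <- function() {
    H <- switch(config$hessian_mode,
      exact = {
        hb <- exact_hessian(env$state, env$cache, fun)
        Hf <- hb$full
        if (identical(config$coupling, "off")) {
          Hf[seq_len(N), N + seq_len(M)] <- 0
          Hf[N + seq_len(M), seq_len(N)] <- 0
        }
        Hf
      },
      cheap = cheap_hessian(env$state, env$cache, fun)$full,
      `cheap+bfgs_nu` = assemble_approx_hessian(
        env$h_cheap, memory, env$map, g_nu_exp = NULL, A = env$A)
    )
    H[subspace, subspace, drop = FALSE]
  }

  accept <- function(p) {
    z <- expand(p)
    if (!is.null(env$trial) && identical(env$trial$p, p)) {
      st <- env$trial$state
      cache <- env$trial$cache
    } else {
      st <- trial_state(z)
      cache <- transform_integrals(system$ao, st$coefficients)
    }
    g_old <- env$grad$vec
    s_n <- st$occupations - env$state$occupations
    env$state <- st
    env$cache <- cache
    env$trial <- NULL
    refresh()
    if (use_bfgs) {
      # quasi-Newton update of the expensive remainder: x-space secant pair
      # with the cheap part subtracted at the new iterate's cheap Hessian
      y_exp <- (env$grad$vec - g_old) -
        as.vector(env$h_cheap$full %*% z)
      nu_bfgs_update(memory, z, y_exp, env$map)
      env$A <- prefactor(s_n, config$tau)
    }
    invisible(NULL)
  }

  list(energy = energy, gradient = gradient, hessian = hessian,
       accept = accept, env = env, dim = length(subspace))
}

# reference-energy registry (best converged energy per tag)
.ref_registry <- new.env(parent = emptyenv())

#' Best converged energy for a tagged system
#'
#' Returns the lowest converged electronic energy recorded for `tag` by any
#' driver run in this session, or `NA` (with attribute `unavailable`) if
#' none converged yet.
#'
#' @param tag character system tag.
#' @return numeric scalar (possibly NA).
#' @export
reference_energy <- function(tag) {
  v <- .ref_registry[[tag]]
  if (is.null(v)) {
    out <- NA_real_
    attr(out, "unavailable") <- TRUE
    return(out)
  }
  v
}

.update_reference <- function(tag, e) {
  if (is.null(tag)) return(invisible(NULL))
  cur <- .ref_registry[[tag]]
  if (is.null(cur) || e < cur) .ref_registry[[tag]] <- e
  invisible(NULL)
}

# shared macro loop; phases = list of subspace index vectors applied in turn
# within each macro iteration (one entry covering everything = 1-step).
.run_driver <- function(system, config, state = NULL, phases, scheme_label) {
  if (is.null(state)) state <- initialize_state(system, beta = config$beta)
  N <- state$n_basis
  M <- state$n_rot
  memory <- if (identical(config$hessian_mode, "cheap+bfgs_nu")) {
    bfgs_memory(N)
  } else NULL
  obj_master <- NULL
  e_cur <- NA_real_
  trace_rows <- list()
  total_eval <- 0L
  converged <- FALSE
  e_prev_macro <- Inf
  macro <- 0L

  current_state <- state
  e_cur <- state_energy(system$ao, current_state, system$functional)
  e_init <- e_cur

  while (macro < config$macro_max) {
    macro <- macro + 1L
    phase_id <- 0L
    grad_norm_full <- Inf
    for (sub in phases) {
      phase_id <- phase_id + 1L
      obj <- .make_objective(system, current_state, config, memory = memory,
                            subspace = sub)
      tr_conf <- config$tr
      tr_conf$gtol <- config$gtol
      tr_conf$max_iter <- config$micro_max
      res <- tr_minimize(obj, dim = length(sub), config = tr_conf, e0 = e_cur)
      current_state <- obj$env$state
      e_cur <- res$energy
      grad_full <- obj$env$grad$vec
      grad_norm_full <- sqrt(sum(grad_full^2))
      if (!is.null(res$trace) && nrow(res$trace) > 0) {
        tr <- res$trace
        tr$iter <- tr$iter + total_eval
        tr$macro <- macro
        tr$phase <- phase_id
        trace_rows[[length(trace_rows) + 1L]] <- tr
      }
      total_eval <- total_eval + res$n_iter
      if (identical(res$status, "non_finite_objective")) {
        warning("aborting: objective returned a non-finite energy")
        macro <- config$macro_max
        break
      }
    }
    de <- e_prev_macro - e_cur
    if (abs(de) < config$etol) {
      converged <- TRUE
      break
    }
    e_prev_macro <- e_cur
    # macro restart: reset the quasi-Newton memory
    if (!is.null(memory)) bfgs_reset(memory)
  }

  trace <- if (length(trace_rows) > 0) do.call(rbind, trace_rows) else NULL
  if (converged) .update_reference(system$tag, e_cur)
  structure(
    list(scheme = scheme_label, converged = converged, energy = e_cur,
         energy_total = e_cur + system$ao$enuc,
         initial_energy = e_init, state = current_state,
         n_iter = total_eval, n_macro = macro, trace = trace,
         grad_norm = if (is.null(trace)) NA_real_ else
           trace$grad_norm[nrow(trace)],
         config = config),
    class = "rdmft_result"
  )
}

#' 1-step optimization: joint occupation and orbital updates
#'
#' Minimizes over the concatenated variables `(x, X^up)` with the configured
#' Hessian mode; on micro convergence the macro loop checks the energy
#' change and, if not yet converged, restarts from the current point with
#' the quasi-Newton memory reset (which regularly rescues approximate-
#' Hessian runs whose memory drifted).
#'
#' @param system an `rdmft_system`.
#' @param config an `rdmft_run_config`.
#' @param state optional starting `rdmft_state` (default: Fermi-Dirac
#'   initialization from the Hartree-Fock reference).
#' @return An `rdmft_result`: final energy (electronic; `energy_total` adds
#'   nuclear repulsion), state, full per-evaluation trace (rejected steps
#'   included), iteration counts, convergence flag.
#' @export
run_one_step <- function(system, config = rdmft_config("one_step"),
                         state = NULL) {
  if (is.null(state)) state <- initialize_state(system, beta = config$beta)
  phases <- list(seq_len(state$n_basis + state$n_rot))
  .run_driver(system, config, state, phases, "one_step")
}

#' 2-step optimization: alternating occupation and orbital phases
#'
#' Each macro iteration fully minimizes over the occupations (orbitals
#' frozen) and then over the orbital rotations (occupations frozen), each
#' phase to the micro gradient tolerance, until the macro energy change
#' drops below tolerance.  Uses the same Hessian machinery restricted to the
#' corresponding diagonal block.
#'
#' @inheritParams run_one_step
#' @return An `rdmft_result`; the trace's `phase` column separates
#'   occupation (1) from orbital (2) phases.
#' @export
run_two_step <- function(system, config = rdmft_config("two_step"),
                         state = NULL) {
  if (is.null(state)) state <- initialize_state(system, beta = config$beta)
  N <- state$n_basis
  M <- state$n_rot
  phases <- list(seq_len(N), N + seq_len(M))
  .run_driver(system, config, state, phases, "two_step")
}

#' First iteration reaching a given error from a reference energy
#'
#' Scans a result's trace for the first objective evaluation after which the
#' current (best accepted) energy is within `tol` of `e_ref`.
#'
#' @param result an `rdmft_result`.
#' @param e_ref reference energy (Hartree, electronic).
#' @param tol error threshold (Hartree).
#' @return iteration index (objective evaluations, rejected steps included),
#'   or NA if never reached.
#' @export
iterations_to_error <- function(result, e_ref, tol) {
  tr <- result$trace
  if (is.null(tr)) return(NA_integer_)
  e_run <- result$initial_energy
  for (i in seq_len(nrow(tr))) {
    if (tr$accepted[i]) e_run <- tr$energy[i]
    if (abs(e_run - e_ref) <= tol) return(tr$iter[i])
  }
  NA_integer_
}
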
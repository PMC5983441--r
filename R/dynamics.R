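#' Evaluate the model right-hand side
#'
#' Time derivative of every node under the Hill-kinetics model: for each
#' node, `a` times the sum of Hill activation fractions of its
#' activators, plus `b` times the sum of Hill inhibition fractions of
#' its inhibitors, minus linear degradation `k * x`. Input sources
#' contribute at their constant levels.
#'
#' @param state named or unnamed numeric state vector in node order.
#' @param network a [grn_network()].
#' @param params a [grn_params()].
#' @return Named derivative vector (per hour).
#' @export
grn_rhs <- function(state, network, params) {
  nn <- length(network$nodes)
  if (length(state) != nn)
    stop("state length (", length(state), ") does not match node count (",
         nn, ")", call. = FALSE)
  m <- network_matrices(network)
  ext <- pmax(c(unname(state), input_levels(params, network)), 0)
  fa <- hill_activation(ext, params$S, params$n)
  fi <- hill_inhibition(ext, params$S, params$n)
  d <- params$a * drop(m$Mact %*% fa) + params$b * drop(m$Minh %*% fi) -
    degradation_vector(params, network) * unname(state)
  stats::setNames(d, network$nodes)
}

#' Analytic Jacobian of the right-hand side
#'
#' Off-diagonal entry (i, j) is the derivative of node i's production
#' with respect to node j: `a * n S^n x_j^(n-1) / (S^n + x_j^n)^2` per
#' activating edge and minus `b` times the same factor per inhibiting
#' edge (the inhibition fraction is the complement of the activation
#' fraction). The diagonal additionally carries `-k`.
#'
#' @inheritParams grn_rhs
#' @return A square matrix (nodes x nodes), per hour.
#' @export
grn_jacobian <- function(state, network, params) {
  nn <- length(network$nodes)
  stopifnot(length(state) == nn)
  m <- network_matrices(network)
  dact <- hill_prime(unname(state), params$S, params$n)
  W <- params$a * m$Mact[, seq_len(nn), drop = FALSE] -
    params$b * m$Minh[, seq_len(nn), drop = FALSE]
  J <- sweep(W, 2L, dact, `*`)
  diag(J) <- diag(J) - degradation_vector(params, network)
  dimnames(J) <- list(network$nodes, network$nodes)
  J
}

#' Integrate the model
#'
#' Solves the initial value problem with deSolve's stiff-capable `lsoda`
#' integrator and a compiled right-hand side, sampling `n_out` evenly
#' spaced times on `[0, t_end]`. Negative solver excursions larger than
#' `-1e-9` are clipped to zero; anything more negative raises an error.
#'
#' @param network a [grn_network()].
#' @param params a [grn_params()].
#' @param x0 initial state (length = number of nodes, all >= 0).
#' @param t_end integration horizon in hours.
#' @param n_out number of output samples (>= 2), evenly spaced.
#' @param times explicit output times overriding `t_end`/`n_out`.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return A `grn_trajectory`: list with `times`, `states` (matrix, one
#'   row per time, columns named by node) and `metadata` (parameters,
#'   initial condition, tolerances).
#' @export
simulate_grn <- function(network, params, x0, t_end = 100, n_out = 201,
                         times = NULL, rtol = 1e-8, atol = 1e-10) {
  nn <- length(network$nodes)
  if (length(x0) != nn)
    stop("x0 length does not match node count", call. = FALSE)
  if (is.null(times)) {
    stopifnot(t_end > 0, n_out >= 2)
    times <- seq(0, t_end, length.out = n_out)
  }
  sol <- integrate_raw(network, params, x0, times, rtol, atol)
  structure(list(times = sol[, 1L],
                 states = clip_negative(sol[, -1L, drop = FALSE]),
                 metadata = list(params = params, x0 = unname(x0),
                                 rtol = rtol, atol = atol)),
            class = "grn_trajectory")
}

# Thin wrapper over deSolve with the compiled derivative function.
integrate_raw <- function(network, params, x0, times, rtol = 1e-8,
                          atol = 1e-10, parms = NULL) {
  if (is.null(parms)) parms <- compiled_parms(network, params)
  y0 <- stats::setNames(pmax(unname(x0), 0), network$nodes)
  sol <- deSolve::lsoda(y0, times, func = "grn_derivs", parms = parms,
                        dllname = "ageingGRN", initfunc = "grn_initmod",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  attr_d <- attributes(sol)$istate
  if (!is.null(attr_d) && attr_d[1L] < 0)
    stop("ODE solver failed near t = ", max(sol[, 1L]), call. = FALSE)
  if (nrow(sol) < length(times))
    stop("ODE solver failed near t = ", max(sol[, 1L]), call. = FALSE)
  sol
}

clip_negative <- function(states, floor = -1e-9) {
  low <- min(states)
  if (low < floor)
    stop("solution went negative (", format(low),
         "); tolerances too loose?", call. = FALSE)
  states[states < 0] <- 0
  states
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "samples on [0,",
      max(x$times), "] h,", ncol(x$states), "species\n")
  invisible(x)
}

#' Sample random initial conditions
#'
#' Draws `n_samples` states with every coordinate independently uniform
#' on `[0, x_max]`. This is the initial-condition ensemble behind the
#' Monte Carlo landscape and the multistart attractor search. Draws are
#' made in a fixed order, so enlarging `n_samples` under the same seed
#' extends the ensemble without re-randomising earlier draws.
#'
#' @param network a [grn_network()] (defines the dimension).
#' @param n_samples number of states to draw.
#' @param x_max upper bound of the per-coordinate uniform range.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return A matrix (`n_samples` x nodes) with named columns.
#' @export
sample_initial_conditions <- function(network, n_samples, x_max = 3,
                                      seed = NULL) {
  stopifnot(n_samples >= 1, x_max > 0)
  nn <- length(network$nodes)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  m <- matrix(stats::runif(n_samples * nn, 0, x_max), nrow = n_samples,
              byrow = TRUE, dimnames = list(NULL, network$nodes))
  m
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Relax a state to steady state
#'
#' Integrates in blocks of `t_block` hours until the derivative
#' max-norm falls below `tol` or `t_max` hours have elapsed.
#' Convergence is measured on the derivative (step-size independent),
#' not on state displacement. Non-convergence is flagged, not raised,
#' so slow or oscillatory dynamics remain reportable.
#'
#' @inheritParams simulate_grn
#' @param t_block block length in hours between convergence checks.
#' @param tol derivative max-norm convergence tolerance (per hour).
#' @param t_max giving-up horizon in hours.
#' @return List with `state` (named endpoint), `converged` (flag),
#'   `t_elapsed` (simulated hours used) and `residual` (final
#'   derivative max-norm).
#' @export
converge_to_steady_state <- function(network, params, x0, t_block = 50,
                                     tol = 1e-8, t_max = 2000,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_block > 0, tol > 0, t_max >= t_block)
  parms <- compiled_parms(network, params)
  x <- pmax(unname(x0), 0)
  elapsed <- 0
  res <- max(abs(grn_rhs(x, network, params)))
  while (res >= tol && elapsed < t_max) {
    sol <- integrate_raw(network, params, x, c(0, t_block), rtol, atol,
                         parms = parms)
    x <- pmax(sol[2L, -1L], 0)
    elapsed <- elapsed + t_block
    res <- max(abs(grn_rhs(x, network, params)))
  }
  list(state = stats::setNames(unname(x), network$nodes),
       converged = res < tol, t_elapsed = elapsed, residual = res)
}

#' Polish a near-fixed point by Newton iteration
#'
#' Damped Newton on the right-hand side with the analytic Jacobian.
#' Used to turn ODE-relaxed endpoints into fixed points accurate to
#' solver-independent precision, and as the corrector inside the
#' continuation code.
#'
#' @inheritParams grn_rhs
#' @param x0 starting state (near a fixed point).
#' @param tol residual max-norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return List with `state`, `converged`, `residual`, `iterations`.
#' @export
refine_fixed_point <- function(x0, network, params, tol = 1e-12,
                               max_iter = 50) {
  x <- pmax(unname(x0), 0)
  for (it in seq_len(max_iter)) {
    f <- grn_rhs(x, network, params)
    res <- max(abs(f))
    if (res < tol)
      return(list(state = stats::setNames(x, network$nodes),
                  converged = TRUE, residual = res, iterations = it - 1L))
    J <- grn_jacobian(x, network, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    # damp so the iterate never leaves the non-negative orthant by much
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (min(xn) > -0.1 || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- pmax(xn, 0)
  }
  f <- grn_rhs(x, network, params)
  list(state = stats::setNames(x, network$nodes),
       converged = max(abs(f)) < tol, residual = max(abs(f)),
       iterations = max_iter)
}

#' Time to reach an attractor
#'
#' First sampled time at which a trajectory comes within a fraction of
#' a target fixed point: `max_i |x_i(t) - x*_i| <= frac * max_i x*_i`
#' (the max-norm distance relative to the attractor's magnitude). `NA`
#' when the trajectory does not reach the target within `t_end`, e.g.
#' because it converges to a different attractor — callers should
#' compare endpoints first.
#'
#' @inheritParams simulate_grn
#' @param target the attractor state (named or plain numeric).
#' @param frac relative closeness threshold (default 1%).
#' @return List with `time` (hours, or `NA`) and `endpoint` (final
#'   state).
#' @export
time_to_attractor <- function(network, params, x0, target, frac = 0.01,
                              t_end = 50, n_out = 501) {
  target <- unname(target)
  tr <- simulate_grn(network, params, x0, t_end = t_end, n_out = n_out)
  d <- apply(abs(sweep(tr$states, 2L, target)), 1L, max)
  hit <- which(d <= frac * max(target))
  list(time = if (length(hit)) tr$times[hit[1L]] else NA_real_,
       endpoint = tr$states[nrow(tr$states), ])
}

#' Write a trajectory as tidy CSV
#'
#' Columns `time` then one column per node; run metadata (parameters,
#' initial condition, tolerances) goes to a JSON sidecar
#' `<file>.meta.json`.
#'
#' @param trajectory a `grn_trajectory` from [simulate_grn()].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  meta <- trajectory$metadata
  meta$params <- unclass(meta$params)
  jsonlite::write_json(meta, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}
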
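#' One-parameter steady-state continuation with fold detection
#'
#' Natural-parameter predictor-corrector: step the parameter, correct
#' the fixed point by Newton iteration seeded from the previous
#' solution. A corrector failure — or a corrected point that jumps away
#' from the branch — triggers step halving; once the step underflows
#' the fold is bracketed by bisection to within `fold_tol` in the
#' parameter and recorded. Works for stable and unstable (saddle)
#' branches alike; stability at each accepted point comes from the
#' Jacobian spectrum.
#'
#' @inheritParams grn_rhs
#' @param param_name parameter to continue in: `a`, `b`, `S`, `k` or an
#'   input name such as `GS`.
#' @param start_value parameter value of the starting fixed point.
#' @param start_state a fixed point at `start_value` (residual < 1e-8).
#' @param direction `+1` to continue upward, `-1` downward.
#' @param step initial parameter step size.
#' @param bounds two-element continuation window; the branch stops at a
#'   bound without recording a fold.
#' @param fold_tol bracketing width for the fold parameter value.
#' @param jump_tol max-coordinate motion of the corrected point above
#'   which the corrector is deemed to have left the branch.
#' @return Object of class `grn_branch`: data frame (`param`, one
#'   column per node, `stable`) with attributes `folds` (parameter
#'   values of detected folds), `param_name`, `direction`.
#' @export
continue_branch <- function(network, params, param_name, start_value,
                            start_state, direction = 1, step = 0.01,
                            bounds = c(0, 2.5), fold_tol = 1e-3,
                            jump_tol = 0.3) {
  stopifnot(direction %in% c(-1, 1), step > 0)
  params <- set_param(params, param_name, start_value)
  if (max(abs(grn_rhs(start_state, network, params))) > 1e-8)
    stop("start_state is not a fixed point at start_value", call. = FALSE)

  corrector <- function(value, x) {
    p <- set_param(params, param_name, value)
    pol <- refine_fixed_point(x, network, p, tol = 1e-11, max_iter = 25)
    if (!pol$converged || max(abs(pol$state - x)) > jump_tol) return(NULL)
    pol$state
  }

  value <- start_value
  x <- stats::setNames(unname(start_state), network$nodes)
  pts <- list(list(value = value, x = x))
  folds <- numeric()
  h <- step
  repeat {
    nxt <- value + direction * h
    if (nxt < bounds[1L] - 1e-12 || nxt > bounds[2L] + 1e-12) {
      nxt <- max(min(nxt, bounds[2L]), bounds[1L])
      if (abs(nxt - value) < 1e-12) break
      xn <- corrector(nxt, x)
      if (!is.null(xn)) {
        value <- nxt; x <- xn
        pts[[length(pts) + 1L]] <- list(value = value, x = x)
      }
      break
    }
    xn <- corrector(nxt, x)
    if (!is.null(xn)) {
      value <- nxt; x <- xn
      pts[[length(pts) + 1L]] <- list(value = value, x = x)
      if (h < step) h <- min(step, h * 2)
    } else {
      if (h <= fold_tol) {
        # bisect [value, nxt] to bracket the fold
        lo <- value; hi <- nxt; xlo <- x
        while (abs(hi - lo) > fold_tol / 2) {
          mid <- (lo + hi) / 2
          xm <- corrector(mid, xlo)
          if (!is.null(xm)) { lo <- mid; xlo <- xm } else hi <- mid
        }
        folds <- c(folds, (lo + hi) / 2)
        break
      }
      h <- h / 2
    }
  }

  states <- do.call(rbind, lapply(pts, `[[`, "x"))
  values <- vapply(pts, `[[`, 0, "value")
  stable <- vapply(seq_along(pts), function(i) {
    p <- set_param(params, param_name, values[i])
    max(Re(eigen(grn_jacobian(states[i, ], network, p),
                 only.values = TRUE)$values)) < 0
  }, TRUE)
  out <- data.frame(param = values, states, stable = stable,
                    check.names = FALSE)
  attr(out, "folds") <- folds
  attr(out, "param_name") <- param_name
  attr(out, "direction") <- direction
  class(out) <- c("grn_branch", "data.frame")
  out
}

#' Fold (saddle-node) parameter values of a branch
#'
#' @param branch a `grn_branch` from [continue_branch()].
#' @return Numeric vector of fold parameter values (possibly empty).
#' @export
branch_folds <- function(branch) attr(branch, "folds")

#' Quasi-static hysteresis sweep
#'
#' At each parameter value the system is relaxed to steady state
#' starting from the previous value's endpoint — the protocol behind
#' slow "going up" / "coming down" parameter ramps. Jumps between the
#' up- and down-sweep reveal the folds and the hysteresis window.
#'
#' @inheritParams continue_branch
#' @param values_up,values_down monotone parameter value sequences for
#'   the two sweeps.
#' @param x0 initial state for the first value of each sweep; default
#'   all-zeros.
#' @return List with data frames `up` and `down` (`param` + node
#'   columns).
#' @export
hysteresis_sweep <- function(network, params, param_name, values_up,
                             values_down, x0 = NULL) {
  if (is.unsorted(values_up) && is.unsorted(rev(values_up)))
    stop("values_up must be monotone", call. = FALSE)
  if (is.unsorted(values_down) && is.unsorted(rev(values_down)))
    stop("values_down must be monotone", call. = FALSE)
  if (is.null(x0)) x0 <- rep(0, length(network$nodes))
  sweep_one <- function(values) {
    x <- x0
    rows <- matrix(NA_real_, length(values), length(network$nodes),
                   dimnames = list(NULL, network$nodes))
    for (i in seq_along(values)) {
      p <- set_param(params, param_name, values[i])
      x <- converge_to_steady_state(network, p, x)$state
      rows[i, ] <- x
    }
    data.frame(param = values, rows, check.names = FALSE)
  }
  list(up = sweep_one(values_up), down = sweep_one(values_down))
}

#' Two-parameter stability-region scan
#'
#' Counts the coexisting stable states on a grid of activation and
#' inhibition rates by brute-force multistart at every grid cell (a
#' shared seed schedule keeps cells comparable). Reports both the
#' number of distinct stable fixed points (`n_states`) and the number
#' of distinct (p53, ATM) cell fates (`n_fates`); the latter is the
#' multistability census in the fate plane (see [fate_census()]).
#'
#' @inheritParams find_attractors
#' @param a_values,b_values grid values of the activation/inhibition
#'   rate.
#' @return Object of class `grn_region_map`: list with matrices
#'   `n_states` and `n_fates` (rows = `a_values`, columns =
#'   `b_values`) and the grids.
#' @export
scan_two_parameters <- function(network, params = grn_params(),
                                a_values, b_values, n_starts = 400,
                                x_max = 3, seed = 1) {
  stopifnot(length(a_values) >= 1, length(b_values) >= 1)
  n_states <- matrix(NA_integer_, length(a_values), length(b_values),
                     dimnames = list(format(a_values), format(b_values)))
  n_fates <- n_states
  for (i in seq_along(a_values)) for (j in seq_along(b_values)) {
    p <- set_param(set_param(params, "a", a_values[i]), "b", b_values[j])
    att <- find_attractors(network, p, n_starts = n_starts,
                           x_max = x_max, seed = seed)
    n_states[i, j] <- sum(att$stable)
    n_fates[i, j] <- nrow(fate_census(att))
  }
  structure(list(a_values = a_values, b_values = b_values,
                 n_states = n_states, n_fates = n_fates),
            class = "grn_region_map")
}

#' @export
print.grn_region_map <- function(x, ...) {
  cat("Stability-region scan (cell-fate counts; rows a, columns b):\n")
  print(x$n_fates)
  invisible(x)
}

#' Cell-cycle activation bifurcation over growth signals
#'
#' Continuation treating the growth-signal input `GS` as the free
#' parameter, tracing the branch structure of a cell-cycle readout
#' (default E2F). Starting from the fixed point reached from the
#' all-zero state at `gs_range[1]`, the branch is continued upward;
#' after a fold the system is relaxed just past it onto the other
#' branch, which is then continued across the full range. Piecewise
#' tracing is repeated until no new fold appears.
#'
#' @inheritParams continue_branch
#' @param readout node whose branch values are of interest (checked to
#'   exist; the full state is returned regardless).
#' @param gs_range continuation window for GS.
#' @param step continuation step in GS.
#' @return List with `branches` (list of `grn_branch`), `folds`
#'   (sorted unique fold GS values) and `readout`.
#' @export
cell_cycle_bifurcation <- function(network, params = grn_params(),
                                   readout = "E2F",
                                   gs_range = c(0, 1), step = 0.005) {
  if (!readout %in% network$nodes)
    stop("readout is not a node: ", readout, call. = FALSE)
  if (!"GS" %in% network$inputs)
    stop("network has no GS input", call. = FALSE)
  p0 <- set_param(params, "GS", gs_range[1L])
  x0 <- refine_fixed_point(
    converge_to_steady_state(network, p0,
                             rep(0, length(network$nodes)))$state,
    network, p0)$state

  branches <- list()
  folds <- numeric()
  frontier <- list(list(value = gs_range[1L], state = x0, direction = 1))
  # a job is redundant when an existing branch already covers the point
  # one step ahead of it (same parameter value, nearby state)
  visited <- function(x, value, direction) {
    probe <- value + direction * 2 * step
    for (br in branches) {
      i <- which.min(abs(br$param - probe))
      if (abs(br$param[i] - probe) < 1.5 * step &&
          max(abs(as.numeric(br[i, network$nodes]) - x)) < 0.05)
        return(TRUE)
    }
    FALSE
  }
  while (length(frontier) && length(branches) < 12L) {
    job <- frontier[[1L]]; frontier <- frontier[-1L]
    if (visited(unname(job$state), job$value, job$direction)) next
    br <- continue_branch(network, params, "GS", job$value, job$state,
                          direction = job$direction, step = step,
                          bounds = gs_range)
    branches[[length(branches) + 1L]] <- br
    for (f in branch_folds(br)) {
      folds <- c(folds, f)
      # relax just past the fold onto the coexisting branch
      nxt <- f + job$direction * max(4 * step, 0.02)
      nxt <- max(min(nxt, gs_range[2L]), gs_range[1L])
      p <- set_param(params, "GS", nxt)
      last <- as.numeric(br[nrow(br), network$nodes])
      xn <- refine_fixed_point(
        converge_to_steady_state(network, p, last)$state, network,
        p)$state
      frontier[[length(frontier) + 1L]] <-
        list(value = nxt, state = xn, direction = job$direction)
      frontier[[length(frontier) + 1L]] <-
        list(value = nxt, state = xn, direction = -job$direction)
    }
  }
  list(branches = branches, folds = sort(unique(round(folds, 6))),
       readout = readout)
}

#' Write a branch as CSV (folds to a JSON sidecar)
#'
#' @param branch a `grn_branch`.
#' @param file CSV path; folds go to `<file>.folds.json`.
#' @return `file`, invisibly.
#' @export
write_branch_csv <- function(branch, file) {
  utils::write.csv(as.data.frame(branch), file, row.names = FALSE)
  jsonlite::write_json(list(param_name = attr(branch, "param_name"),
                            folds = branch_folds(branch)),
                       paste0(file, ".folds.json"), digits = NA)
  invisible(file)
}

#' Write a region map as CSV
#'
#' Fate-count matrix with `a` values as rows and `b` values as columns.
#'
#' @param region a `grn_region_map`.
#' @param file CSV path.
#' @param which `"n_fates"` (default) or `"n_states"`.
#' @return `file`, invisibly.
#' @export
write_region_csv <- function(region, file, which = "n_fates") {
  m <- region[[which]]
  utils::write.csv(data.frame(a = region$a_values, m,
                              check.names = FALSE),
                   file, row.names = FALSE)
  invisible(file)
}
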
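#' Kinetic parameter set
#'
#' Global kinetic constants of the Hill-kinetics model plus the constant
#' input levels. All concentrations are dimensionless; rates are per
#' hour. The defaults are the model's reference parameterisation:
#' `S = 0.5`, `n = 4`, `k = 1`, `a = 1`, `b = 0.05`, `Stress = 0.3`,
#' `GS = 0.2`.
#'
#' * `a` — activation rate, one global coefficient scaling every
#'   activating production term. Biologically interpreted as the level
#'   of accumulated DNA damage: it is the main bifurcation parameter.
#' * `b` — inhibition rate, scaling every inhibitory (basal) production
#'   term.
#' * `S` — Hill threshold (regulation strength), `n` — Hill coefficient.
#' * `k` — linear degradation rate; a scalar applied to every node, or a
#'   named per-node vector.
#' * `inputs` — named levels of the constant inputs (`Stress`, `GS` for
#'   the built-in network).
#'
#' @param a,b,S,n,k numeric kinetic constants, see details.
#' @param inputs named numeric vector of constant input levels.
#' @return An object of class `grn_params`.
#' @export
grn_params <- function(a = 1, b = 0.05, S = 0.5, n = 4, k = 1,
                       inputs = c(Stress = 0.3, GS = 0.2)) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0,
            is.numeric(b), length(b) == 1L, b >= 0,
            is.numeric(S), length(S) == 1L, S > 0,
            is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(k), all(k > 0))
  if (length(inputs) && is.null(names(inputs)))
    stop("inputs must be a named numeric vector", call. = FALSE)
  if (any(inputs < 0)) stop("input levels must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, S = S, n = n, k = k,
                 inputs = inputs),
            class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  kfmt <- if (length(x$k) == 1L) format(x$k) else
    paste(names(x$k), format(x$k), sep = "=", collapse = ", ")
  cat("Hill-kinetics parameters: a =", x$a, " b =", x$b,
      " S =", x$S, " n =", x$n, " k =", kfmt, "\n")
  cat("Inputs:", paste(names(x$inputs), x$inputs, sep = " = ",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Modify one parameter or input level
#'
#' Convenience used throughout continuation and scanning code: `name`
#' may be one of `a`, `b`, `S`, `n`, `k` or the name of a constant input
#' (e.g. `GS`).
#'
#' @param params a [grn_params()].
#' @param name parameter or input name.
#' @param value new numeric value.
#' @return The modified `grn_params`.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "grn_params"))
  if (name %in% c("a", "b", "S", "n", "k")) {
    params[[name]] <- value
  } else if (name %in% names(params$inputs)) {
    params$inputs[[name]] <- value
  } else {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  do.call(grn_params, unclass(params))
}

get_param <- function(params, name) {
  if (name %in% c("a", "b", "S", "n", "k")) params[[name]]
  else if (name %in% names(params$inputs)) params$inputs[[name]]
  else stop("unknown parameter: ", name, call. = FALSE)
}

# Per-node degradation vector in node order.
degradation_vector <- function(params, network) {
  k <- params$k
  if (length(k) == 1L) return(rep(k, length(network$nodes)))
  if (is.null(names(k)) || !all(network$nodes %in% names(k)))
    stop("per-node k must be named and cover every node", call. = FALSE)
  unname(k[network$nodes])
}

# Input levels aligned with network$inputs.
input_levels <- function(params, network) {
  if (!all(network$inputs %in% names(params$inputs)))
    stop("parameter set lacks level(s) for input(s): ",
         paste(setdiff(network$inputs, names(params$inputs)),
               collapse = ", "), call. = FALSE)
  unname(params$inputs[network$inputs])
}

# Flatten network + parameters into the vector consumed by the compiled
# right-hand side (see src/grn_derivs.c for the layout). deSolve's
# compiled-model interface requires a fixed-length parameter vector, so
# the tail is zero-padded to the size the DLL declares.
GRN_MAX_PARMS <- 8192L

compiled_parms <- function(network, params) {
  m <- network_matrices(network)
  nn <- length(network$nodes)
  pv <- c(nn, length(network$inputs), params$a, params$b, params$S,
          params$n,
          degradation_vector(params, network),
          input_levels(params, network),
          as.numeric(m$Mact), as.numeric(m$Minh))
  if (length(pv) > GRN_MAX_PARMS)
    stop("network too large for the compiled right-hand side", call. = FALSE)
  c(pv, numeric(GRN_MAX_PARMS - length(pv)))
}

#' Read or write a parameter configuration file
#'
#' Flat key-value JSON with keys `a`, `b`, `S`, `n`, `k` and one key per
#' input level (lower- or exact-case input names both accepted on read).
#'
#' @param params a [grn_params()].
#' @param file path of the JSON file.
#' @return `read_params_json()` returns a [grn_params()].
#' @export
write_params_json <- function(params, file) {
  x <- c(list(a = params$a, b = params$b, S = params$S, n = params$n,
              k = params$k), as.list(params$inputs))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  known <- c("a", "b", "S", "n", "k")
  inputs <- x[setdiff(names(x), known)]
  names(inputs) <- map_input_names(names(inputs))
  args <- x[intersect(names(x), known)]
  args$inputs <- unlist(inputs)
  do.call(grn_params, args)
}

map_input_names <- function(nm) {
  canon <- c(stress = "Stress", gs = "GS")
  out <- canon[tolower(nm)]
  ifelse(is.na(out), nm, out)
}
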
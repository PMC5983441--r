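#' Hill activation kinetics
#'
#' Sigmoidal activation fraction `x^n / (S^n + x^n)` used for every
#' activating interaction in the network model. `S` is the regulation
#' threshold (the concentration at half-maximal activation) and `n` the
#' Hill coefficient controlling steepness (cooperativity of binding).
#'
#' @param x non-negative regulator concentration(s), dimensionless.
#' @param S Hill threshold, must be positive.
#' @param n Hill coefficient, must be >= 1.
#' @return Activation fraction in `[0, 1)`, same length as `x`.
#' @seealso [hill_inhibition()], which is its complement:
#'   `hill_activation(x) + hill_inhibition(x) == 1`.
#' @examples
#' hill_activation(0.5, S = 0.5, n = 4)  # half-saturation: 0.5
#' @export
hill_activation <- function(x, S, n) {
  check_hill_args(x, S, n)
  xn <- x^n
  xn / (S^n + xn)
}

#' Hill inhibition kinetics
#'
#' Sigmoidal inhibition fraction `S^n / (S^n + x^n)`: the basal
#' production allowed through by an inhibitor at concentration `x`.
#' Equals 1 in the absence of inhibitor and decays to 0 as `x` grows.
#'
#' @inheritParams hill_activation
#' @return Inhibition fraction in `(0, 1]`, same length as `x`.
#' @export
hill_inhibition <- function(x, S, n) {
  check_hill_args(x, S, n)
  Sn <- S^n
  Sn / (Sn + x^n)
}

check_hill_args <- function(x, S, n) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("Hill kinetics require finite non-negative concentrations", call. = FALSE)
  if (!is.numeric(S) || length(S) != 1L || S <= 0)
    stop("Hill threshold S must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("Hill coefficient n must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# Derivative of the activation fraction w.r.t. x; the inhibition fraction
# has derivative -hill_prime. Used by the analytic Jacobian.
hill_prime <- function(x, S, n) {
  x <- pmax(x, 0)
  Sn <- S^n
  n * Sn * x^(n - 1) / (Sn + x^n)^2
}
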
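#' Identify attractors by seeded multistart
#'
#' Relaxes `n_starts` random initial states to steady state
#' ([converge_to_steady_state()]), polishes each endpoint by Newton
#' iteration ([refine_fixed_point()]), clusters the resulting fixed
#' points (max-coordinate distance below `cluster_tol`), and keeps
#' every cluster together with its Jacobian spectrum, stability flag,
#' basin fraction (share of converged starts) and phenotype label.
#' Deterministic under a fixed seed.
#'
#' Note that distinct stable fixed points need not be distinct cell
#' fates: the Rb-E2F module is a self-contained bistable switch driven
#' (but not fed back) by the p53 arm, so a quiescent and a
#' proliferative variant of the same (p53, ATM) fate can coexist. Use
#' [fate_census()] to group attractors by their phenotype-plane
#' projection.
#'
#' @inheritParams converge_to_steady_state
#' @param n_starts number of random starts.
#' @param x_max upper bound of the uniform initial-condition range.
#' @param seed integer seed for the start ensemble.
#' @param cluster_tol max-coordinate distance under which two polished
#'   fixed points are the same attractor.
#' @param thresholds phenotype thresholds, see [classify_phenotype()];
#'   `NULL` uses the canonical defaults when applicable.
#' @return Object of class `grn_attractors`: list with `states` (matrix,
#'   one row per fixed point), `stable`, `spectral_abscissa`,
#'   `eigenvalues` (list), `basin_fraction`, `phenotype`,
#'   `n_unconverged`, and the search settings.
#' @export
find_attractors <- function(network, params, n_starts = 1000, x_max = 3,
                            seed = 1, cluster_tol = 1e-3, t_block = 50,
                            tol = 1e-8, t_max = 2000, thresholds = NULL) {
  stopifnot(n_starts >= 1)
  starts <- sample_initial_conditions(network, n_starts, x_max, seed)
  fixed <- list()
  hits <- integer()
  n_unconverged <- 0L
  for (i in seq_len(n_starts)) {
    cv <- converge_to_steady_state(network, params, starts[i, ],
                                   t_block = t_block, tol = tol,
                                   t_max = t_max)
    if (!cv$converged) { n_unconverged <- n_unconverged + 1L; next }
    pol <- refine_fixed_point(cv$state, network, params)
    if (!pol$converged) { n_unconverged <- n_unconverged + 1L; next }
    idx <- match_cluster(pol$state, fixed, cluster_tol)
    if (is.na(idx)) {
      fixed[[length(fixed) + 1L]] <- pol$state
      hits[length(fixed)] <- 1L
    } else {
      hits[idx] <- hits[idx] + 1L
    }
  }
  build_attractors(fixed, hits, n_unconverged, network, params,
                   thresholds,
                   settings = list(n_starts = n_starts, x_max = x_max,
                                   seed = seed, cluster_tol = cluster_tol))
}

match_cluster <- function(state, fixed, tol) {
  for (j in seq_along(fixed))
    if (max(abs(state - fixed[[j]])) < tol) return(j)
  NA_integer_
}

build_attractors <- function(fixed, hits, n_unconverged, network, params,
                             thresholds, settings) {
  nn <- length(network$nodes)
  states <- matrix(NA_real_, length(fixed), nn,
                   dimnames = list(NULL, network$nodes))
  eig <- vector("list", length(fixed))
  for (j in seq_along(fixed)) {
    states[j, ] <- fixed[[j]]
    eig[[j]] <- eigen(grn_jacobian(fixed[[j]], network, params),
                      only.values = TRUE)$values
  }
  abscissa <- vapply(eig, function(e) max(Re(e)), 0)
  stable <- abscissa < 0
  total <- sum(hits)
  basin <- if (total > 0) hits / total else rep(NA_real_, length(hits))
  pheno <- vapply(seq_along(fixed), function(j)
    classify_phenotype(states[j, ], thresholds), "")
  ord <- order(states[, "p53"])
  structure(list(states = states[ord, , drop = FALSE],
                 stable = stable[ord],
                 spectral_abscissa = abscissa[ord],
                 eigenvalues = eig[ord],
                 basin_fraction = basin[ord],
                 phenotype = pheno[ord],
                 n_unconverged = n_unconverged,
                 network = network, params = params,
                 settings = settings),
            class = "grn_attractors")
}

#' @export
print.grn_attractors <- function(x, ...) {
  cat("Fixed points found:", nrow(x$states),
      "(", sum(x$stable), "stable ),",
      x$n_unconverged, "unconverged starts\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.grn_attractors <- function(x, ...) {
  data.frame(x$states,
             stable = x$stable,
             spectral_abscissa = x$spectral_abscissa,
             basin_fraction = x$basin_fraction,
             phenotype = x$phenotype,
             check.names = FALSE)
}

#' Group attractors into cell fates
#'
#' The model's cell fates are defined by the (p53, ATM) marker pair.
#' Because the Rb-E2F cell-cycle switch is bistable independently of
#' those markers, several stable fixed points can share one fate. This
#' groups the stable attractors whose projections onto `coords` agree
#' within `tol`, summing basin fractions.
#'
#' @param attractors a `grn_attractors` object.
#' @param coords the two (or more) fate-defining coordinates.
#' @param tol absolute agreement tolerance per coordinate.
#' @return Data frame with one row per fate: the projected coordinates,
#'   pooled `basin_fraction`, member count `n_states`, and `phenotype`.
#' @export
fate_census <- function(attractors, coords = c("p53", "ATM"), tol = 0.05) {
  stopifnot(inherits(attractors, "grn_attractors"))
  keep <- attractors$stable
  proj <- attractors$states[keep, coords, drop = FALSE]
  basin <- attractors$basin_fraction[keep]
  pheno <- attractors$phenotype[keep]
  groups <- integer(nrow(proj))
  reps <- list()
  for (i in seq_len(nrow(proj))) {
    g <- NA_integer_
    for (j in seq_along(reps))
      if (max(abs(proj[i, ] - reps[[j]])) < tol) { g <- j; break }
    if (is.na(g)) { reps[[length(reps) + 1L]] <- proj[i, ]; g <- length(reps) }
    groups[i] <- g
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(g) {
    m <- groups == g
    data.frame(as.list(colMeans(proj[m, , drop = FALSE])),
               basin_fraction = sum(basin[m]),
               n_states = sum(m),
               phenotype = pheno[which(m)[1L]],
               check.names = FALSE)
  }))
  out[order(out[[coords[1L]]]), , drop = FALSE]
}

#' Classify a state into a cell phenotype
#'
#' Labels depend only on the (p53, ATM) coordinates:
#' * `homeostasis` — p53 low and ATM low;
#' * `cell_cycle_arrest` — p53 intermediate and ATM low;
#' * `senescence_or_apoptosis` — p53 high and ATM high;
#' * `cancer` — p53 low and ATM high;
#' * `unclassified` — anything else.
#'
#' `thresholds` is a list with `p53_low` (low | intermediate cut),
#' `p53_high` (intermediate | high cut) and `atm` (low | high cut). The
#' default thresholds are computed once from the built-in network at
#' the reference parameterisation (see [phenotype_thresholds()]) and
#' cached; they apply to any parameter set since labels are a fixed
#' partition of the marker plane.
#'
#' @param state full named state vector, or a named vector containing at
#'   least `p53` and `ATM`.
#' @param thresholds threshold list as above, or `NULL` for the cached
#'   canonical defaults.
#' @return A single phenotype label string.
#' @export
classify_phenotype <- function(state, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- phenotype_thresholds()
  if (!(thresholds$p53_low < thresholds$p53_high))
    stop("phenotype thresholds must satisfy p53_low < p53_high",
         call. = FALSE)
  p53 <- unname(state[["p53"]])
  atm <- unname(state[["ATM"]])
  atm_low <- atm < thresholds$atm
  if (p53 < thresholds$p53_low) {
    if (atm_low) "homeostasis" else "cancer"
  } else if (p53 < thresholds$p53_high) {
    if (atm_low) "cell_cycle_arrest" else "unclassified"
  } else {
    if (atm_low) "unclassified" else "senescence_or_apoptosis"
  }
}

.ageingGRN_cache <- new.env(parent = emptyenv())

#' Default phenotype thresholds from the model's bifurcation structure
#'
#' The p53 low/intermediate cut is the midpoint between the low and
#' intermediate p53 branch levels at activation rate `a = 1`, the
#' intermediate/high cut the midpoint between the intermediate and high
#' branch levels there, and the ATM cut the midpoint of ATM's bimodal
#' attractor values (both realised at `a = 1`, where ATM is bistable).
#' The three reference fixed points are obtained deterministically by
#' relaxing targeted initial states of the built-in network and
#' polishing. Results are cached for the session.
#'
#' @param network,params the network/parameterisation from which to
#'   derive the cuts; defaults to the built-in model at its reference
#'   parameters with `a = 1`.
#' @return List with `p53_low`, `p53_high`, `atm`.
#' @export
phenotype_thresholds <- function(network = NULL, params = NULL) {
  key <- "canonical"
  if (is.null(network) && is.null(params) &&
      !is.null(.ageingGRN_cache[[key]]))
    return(.ageingGRN_cache[[key]])
  canonical <- is.null(network) && is.null(params)
  if (is.null(network)) network <- ageing_network()
  if (is.null(params)) params <- grn_params(a = 1)
  nn <- length(network$nodes)
  fp <- function(x0) {
    cv <- converge_to_steady_state(network, params, x0)
    refine_fixed_point(cv$state, network, params)$state
  }
  low <- fp(rep(0, nn))
  mid0 <- stats::setNames(rep(0.1, nn), network$nodes)
  mid0[c("p53", "Wip1", "p21", "PTEN")] <- 1
  mid <- fp(mid0)
  high <- fp(rep(2, nn))
  th <- list(p53_low = mean(c(low[["p53"]], mid[["p53"]])),
             p53_high = mean(c(mid[["p53"]], high[["p53"]])),
             atm = mean(c(mid[["ATM"]], high[["ATM"]])))
  if (canonical) .ageingGRN_cache[[key]] <- th
  th
}

#' Locate a saddle point between two attractors
#'
#' Bisects along the straight segment between two attractor states on
#' basin membership of the relaxed endpoint, follows the resulting
#' near-boundary state towards the saddle (trajectories from the basin
#' boundary approach the saddle along its stable manifold), takes the
#' trajectory point of smallest derivative norm and polishes it by
#' Newton iteration.
#'
#' @inheritParams grn_rhs
#' @param x1,x2 two attractor states (named vectors or rows).
#' @param n_bisect bisection iterations on the segment parameter.
#' @return List with `state` (the saddle), `residual`, `eigenvalues`
#'   and `n_unstable` (count of eigenvalues with positive real part).
#' @export
find_saddle <- function(network, params, x1, x2, n_bisect = 40) {
  x1 <- unname(x1); x2 <- unname(x2)
  closer_to_x1 <- function(x) max(abs(x - x1)) < max(abs(x - x2))
  lo <- 0; hi <- 1
  for (i in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    xe <- converge_to_steady_state(network, params,
                                   (1 - mid) * x1 + mid * x2)$state
    if (closer_to_x1(xe)) lo <- mid else hi <- mid
  }
  x0 <- (1 - (lo + hi) / 2) * x1 + ((lo + hi) / 2) * x2
  traj <- simulate_grn(network, params, x0, t_end = 60, n_out = 600)
  resn <- apply(traj$states, 1L, function(s)
    max(abs(grn_rhs(s, network, params))))
  # the near-boundary trajectory approaches the saddle (residual dips),
  # leaves it, then settles into an attractor (residual dips again):
  # the saddle is the FIRST dip of the residual, never the last
  rising <- which(diff(resn) > 0)
  dip_end <- if (length(rising)) rising[1L] else length(resn)
  at_saddle <- which.min(resn[seq_len(dip_end)])
  pol <- refine_fixed_point(traj$states[at_saddle, ], network,
                            params, tol = 1e-12)
  ev <- eigen(grn_jacobian(pol$state, network, params),
              only.values = TRUE)$values
  list(state = pol$state, residual = pol$residual, eigenvalues = ev,
       n_unstable = sum(Re(ev) > 0))
}

#' Write the attractor table as CSV
#'
#' One row per fixed point: all coordinates, stability flag, spectral
#' abscissa, basin fraction and phenotype.
#'
#' @param attractors a `grn_attractors` object.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_attractors_csv <- function(attractors, file) {
  utils::write.csv(as.data.frame(attractors), file, row.names = FALSE)
  invisible(file)
}
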
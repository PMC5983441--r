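#' Monte Carlo quasi-potential landscape
#'
#' Estimates the quasi-potential U = -ln P(x) over a two-dimensional
#' projection of state space. `n_traj` trajectories are integrated from
#' seeded uniform random initial conditions; every sampled time point
#' of every trajectory — transient and equilibrium alike — is projected
#' onto the two coordinate nodes and binned on a regular grid. P is the
#' visit fraction per box and U its negative logarithm; boxes never
#' visited carry the capped value `max(finite U) + 1` and are flagged.
#'
#' Because late-time samples of every trajectory sit in an attractor
#' box, attractors appear as deep minima; slow transient regions (for
#' example the remnant of a just-vanished fixed point after a
#' saddle-node bifurcation) also accumulate probability and can appear
#' as shallower basins. That time-weighted definition is intentional:
#' the landscape describes where the dynamics spends time, not only
#' where it ends.
#'
#' Projected values at or beyond `axis_max` are binned into the last
#' box (the grid clamps rather than discards, so P always sums to 1).
#'
#' @inheritParams simulate_grn
#' @param coords two distinct node names spanning the projection plane.
#' @param n_traj number of Monte Carlo trajectories.
#' @param t_end horizon of each trajectory (hours).
#' @param n_samples_per_traj evenly spaced samples per trajectory.
#' @param n_boxes boxes per axis.
#' @param x_max upper bound of the uniform initial-condition range and
#'   of both grid axes.
#' @param seed integer seed for the initial-condition ensemble.
#' @return Object of class `grn_landscape`: list with `coords`,
#'   `breaks`, `mids`, matrices `counts`, `P`, `U` (rows = first
#'   coordinate), `empty` (logical matrix), `U_cap` and `metadata`.
#' @export
estimate_landscape <- function(network, params, coords = c("p53", "ATM"),
                               n_traj = 10000, t_end = 50,
                               n_samples_per_traj = 500, n_boxes = 100,
                               x_max = 3, seed = 1, rtol = 1e-8,
                               atol = 1e-10) {
  stopifnot(length(coords) == 2L, n_traj >= 1)
  if (!all(coords %in% network$nodes))
    stop("coords must be nodes: ",
         paste(setdiff(coords, network$nodes), collapse = ", "),
         call. = FALSE)
  if (coords[1L] == coords[2L]) stop("coords must be distinct", call. = FALSE)
  ci <- match(coords, network$nodes)
  starts <- sample_initial_conditions(network, n_traj, x_max, seed)
  times <- seq(0, t_end, length.out = n_samples_per_traj)
  parms <- compiled_parms(network, params)
  counts <- numeric(n_boxes * n_boxes)
  traj_count <- numeric(n_boxes * n_boxes)
  width <- x_max / n_boxes
  for (i in seq_len(n_traj)) {
    sol <- integrate_raw(network, params, starts[i, ], times, rtol, atol,
                         parms = parms)
    bx <- pmin(pmax(floor(sol[, 1L + ci[1L]] / width), 0), n_boxes - 1)
    by <- pmin(pmax(floor(sol[, 1L + ci[2L]] / width), 0), n_boxes - 1)
    idx <- bx + n_boxes * by + 1
    counts <- counts + tabulate(idx, nbins = n_boxes * n_boxes)
    u <- unique(idx)
    traj_count[u] <- traj_count[u] + 1
  }
  counts <- matrix(counts, n_boxes, n_boxes)  # rows: coord 1, cols: coord 2
  traj_count <- matrix(traj_count, n_boxes, n_boxes)
  P <- counts / sum(counts)
  U <- matrix(NA_real_, n_boxes, n_boxes)
  pos <- P > 0
  U[pos] <- -log(P[pos])
  U_cap <- max(U[pos]) + 1
  U[!pos] <- U_cap
  mids <- (seq_len(n_boxes) - 0.5) * width
  structure(list(coords = coords,
                 breaks = seq(0, x_max, by = width), mids = mids,
                 counts = counts, traj_count = traj_count, P = P, U = U,
                 empty = !pos, U_cap = U_cap,
                 metadata = list(n_traj = n_traj, t_end = t_end,
                                 n_samples_per_traj = n_samples_per_traj,
                                 n_boxes = n_boxes, x_max = x_max,
                                 seed = seed, params = params)),
            class = "grn_landscape")
}

#' @export
print.grn_landscape <- function(x, ...) {
  cat("Quasi-potential landscape over (", x$coords[1L], ", ",
      x$coords[2L], "): ", nrow(x$U), "x", ncol(x$U), " boxes, ",
      x$metadata$n_traj, " trajectories\n", sep = "")
  invisible(x)
}

#' Locate basins (local minima of U)
#'
#' Finds boxes whose potential is strictly below all 8 neighbours,
#' merges minima closer than `min_separation` boxes (Chebyshev
#' distance, keeping the deeper one), and filters shallow Monte Carlo
#' speckle by topographic persistence: a minimum is kept only if the
#' barrier separating it from any deeper minimum exceeds
#' `min_persistence` in U units (1 unit = an e-fold probability
#' contrast). Persistence is computed exactly by a union-find sweep of
#' the boxes in order of increasing U.
#'
#' Two sampling-noise filters guard the census. First, a basin box must
#' hold at least `min_count` samples: the initial-condition scatter
#' sprinkles every box with a few one-off samples, and local Poisson
#' maxima of that sprinkle would otherwise masquerade as minima (the
#' floor scales with the total sample count: 4 per million, at least
#' 10). Second, the box must have been visited by at least `min_traj`
#' distinct trajectories: a single slow trajectory deposits many
#' samples wherever it crawls, whatever the ensemble size, so a count
#' floor alone cannot reject single-trajectory debris — a basin is an
#' ensemble feature (floor 0.05% of trajectories, at least 3).
#'
#' Detection runs on a lightly smoothed potential: counts are averaged
#' over a `(2*smooth+1)^2` boxcar window before taking `-log`, which
#' flattens the one-off Poisson sprinkle of initial conditions and
#' early transients (whose local maxima would otherwise masquerade as
#' minima) while leaving the concentrated mass of real basins intact.
#' Reported `U` values are taken from the raw potential at the
#' detected box.
#'
#' @param grid a `grn_landscape`.
#' @param min_separation merge radius in boxes.
#' @param min_persistence minimum barrier height (in U units, on the
#'   smoothed potential) for a basin to count; the global minimum is
#'   always kept.
#' @param smooth half-width of the boxcar smoothing window used for
#'   detection (0 disables smoothing).
#' @param min_count minimum sample count in a basin's window; `NULL`
#'   for the scaled default (4 per million samples, at least 10).
#' @param min_traj minimum number of distinct trajectories that must
#'   have visited a basin's box; `NULL` for the scaled default (0.05%
#'   of trajectories, at least 3).
#' @return Data frame sorted by U ascending: box indices `ix`, `iy`,
#'   coordinates (box centres), `U`, `count`, `n_traj` (distinct
#'   visiting trajectories), `persistence`.
#' @export
locate_basins <- function(grid, min_separation = 5, min_persistence = 1,
                          smooth = 1, min_count = NULL, min_traj = NULL) {
  stopifnot(inherits(grid, "grn_landscape"))
  if (is.null(min_count))
    min_count <- max(10, 4e-6 * sum(grid$counts))
  if (is.null(min_traj))
    min_traj <- max(3, 5e-4 * grid$metadata$n_traj)
  nb <- nrow(grid$U)
  cs <- smooth_matrix(grid$counts, smooth)
  Us <- matrix(NA_real_, nb, nb)
  pos <- cs > 0
  Us[pos] <- -log(cs[pos] / sum(grid$counts))
  Us[!pos] <- max(Us[pos]) + 1
  per <- persistence_minima(Us)
  # snap each smoothed minimum to the most-visited raw box inside its
  # smoothing window (the smoothed argmin can drift one box off the
  # attractor cell because every neighbour's window contains it)
  if (smooth > 0 && nrow(per)) {
    for (i in seq_len(nrow(per))) {
      rs <- max(1, per$ix[i] - smooth):min(nb, per$ix[i] + smooth)
      csel <- max(1, per$iy[i] - smooth):min(nb, per$iy[i] + smooth)
      w <- grid$counts[rs, csel, drop = FALSE]
      hit <- arrayInd(which.max(w), dim(w))
      per$ix[i] <- rs[hit[1L]]
      per$iy[i] <- csel[hit[2L]]
    }
  }
  keep <- per$persistence >= min_persistence | per$is_global
  # never report empty-box plateaus, Poisson sprinkle, or
  # single-trajectory debris
  keep <- keep & !grid$empty[cbind(per$ix, per$iy)]
  keep <- keep & cs[cbind(per$ix, per$iy)] >= min_count
  keep <- keep & grid$traj_count[cbind(per$ix, per$iy)] >= min_traj
  per <- per[keep, , drop = FALSE]
  per$U <- grid$U[cbind(per$ix, per$iy)]
  per <- per[order(per$U), , drop = FALSE]
  # merge near-coincident minima, deeper one wins
  taken <- rep(TRUE, nrow(per))
  for (i in seq_len(nrow(per))) {
    if (!taken[i]) next
    if (i < nrow(per)) for (j in (i + 1L):nrow(per)) {
      if (taken[j] &&
          max(abs(c(per$ix[i] - per$ix[j], per$iy[i] - per$iy[j]))) <
          min_separation)
        taken[j] <- FALSE
    }
  }
  per <- per[taken, , drop = FALSE]
  out <- data.frame(ix = per$ix, iy = per$iy,
                    x = grid$mids[per$ix], y = grid$mids[per$iy],
                    U = per$U,
                    count = grid$counts[cbind(per$ix, per$iy)],
                    n_traj = grid$traj_count[cbind(per$ix, per$iy)],
                    persistence = per$persistence)
  names(out)[3:4] <- grid$coords
  rownames(out) <- NULL
  out
}

# Boxcar window sum: each cell becomes the sum of the (2h+1)^2 window
# around it (truncated at the borders).
smooth_matrix <- function(m, h) {
  if (h <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rd <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    cd <- max(1, 1 - dc):min(nc, nc - dc)
    out[rd, cd] <- out[rd, cd] + m[rs, cs]
  }
  out
}

# Sublevel-set persistence of local minima on an 8-connected grid.
# Returns every local minimum with the U level at which its component
# merges into a deeper one (persistence = merge level - minimum level;
# Inf for the global minimum).
persistence_minima <- function(U) {
  nb_r <- nrow(U); nb_c <- ncol(U)
  n <- nb_r * nb_c
  ord <- order(as.numeric(U))
  parent <- integer(n)            # 0 = not yet born
  min_of <- integer(n)            # root -> index of its minimum cell
  birth <- numeric(n)             # root -> birth level
  death <- rep(Inf, n)            # minimum cell -> merge level
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (cell in ord) {
    r <- (cell - 1L) %% nb_r + 1L
    c <- (cell - 1L) %/% nb_r + 1L
    lvl <- U[cell]
    roots <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > nb_r || cc < 1L || cc > nb_c) next
      nb <- (cc - 1L) * nb_r + rr
      if (parent[nb] != 0L) roots <- c(roots, find(nb))
    }
    roots <- unique(roots)
    if (length(roots) == 0L) {
      parent[cell] <- cell
      min_of[cell] <- cell
      birth[cell] <- lvl
    } else {
      # attach to the oldest (deepest-born) component; others die here
      main <- roots[which.min(birth[roots])]
      for (rt in roots) {
        if (rt != main) {
          death[min_of[rt]] <- lvl
          parent[rt] <- main
        }
      }
      parent[cell] <- main
    }
  }
  # component minima are exactly the cells that were born as their own
  # component (min_of[cell] == cell)
  born <- which(vapply(seq_len(n), function(i)
    parent[i] != 0L && min_of[i] == i, TRUE))
  res <- data.frame(
    ix = (born - 1L) %% nb_r + 1L,
    iy = (born - 1L) %/% nb_r + 1L,
    U = U[born],
    persistence = death[born] - U[born],
    is_global = !is.finite(death[born])
  )
  res
}

#' Rank basins by depth and phenotype
#'
#' Orders the basins of [locate_basins()] by potential (deepest first)
#' and labels each with a phenotype. When the landscape's coordinates
#' are the phenotype markers (p53, ATM) the label comes directly from
#' the basin's box-centre coordinates — this also labels basins formed
#' by slow transient regions that have no corresponding fixed point.
#' Otherwise attractors must be supplied and the nearest attractor (in
#' the projection plane) provides the label.
#'
#' @param grid a `grn_landscape`.
#' @param minima data frame from [locate_basins()].
#' @param attractors optional `grn_attractors` for non-marker
#'   coordinate pairs.
#' @param thresholds see [classify_phenotype()].
#' @return The `minima` data frame sorted by `U` ascending with a
#'   `phenotype` column added.
#' @export
basin_depth_rank <- function(grid, minima, attractors = NULL,
                             thresholds = NULL) {
  stopifnot(nrow(minima) >= 1)
  if (setequal(grid$coords, c("p53", "ATM"))) {
    lab <- vapply(seq_len(nrow(minima)), function(i) {
      st <- c(minima[[grid$coords[1L]]][i], minima[[grid$coords[2L]]][i])
      names(st) <- grid$coords
      classify_phenotype(st, thresholds)
    }, "")
  } else {
    if (is.null(attractors))
      stop("attractors required to label basins on coordinates other ",
           "than (p53, ATM)", call. = FALSE)
    proj <- attractors$states[, grid$coords, drop = FALSE]
    lab <- vapply(seq_len(nrow(minima)), function(i) {
      d <- sqrt((proj[, 1L] - minima[[grid$coords[1L]]][i])^2 +
                (proj[, 2L] - minima[[grid$coords[2L]]][i])^2)
      attractors$phenotype[which.min(d)]
    }, "")
  }
  out <- minima
  out$phenotype <- lab
  out[order(out$U), , drop = FALSE]
}

#' Heteroclinic path from a saddle point
#'
#' Integrates forward from `saddle +/- eps * v` where `v` is the
#' unstable eigenvector, producing the two halves of the saddle's
#' unstable manifold. Each half converges to an attractor; their
#' projections onto the landscape plane trace the kinetic path
#' connecting the two basins through the saddle.
#'
#' @inheritParams simulate_grn
#' @param saddle an unstable fixed point with exactly one Jacobian
#'   eigenvalue of positive real part (e.g. from [find_saddle()]).
#' @param coords two node names for the projection.
#' @param eps initial displacement along the unstable eigenvector.
#' @param t_end integration horizon per half.
#' @return List of two data frames (`plus`, `minus`), each with the
#'   projected path columns and an `endpoint` attribute (full final
#'   state).
#' @export
saddle_path <- function(network, params, saddle, coords = c("p53", "ATM"),
                        eps = 1e-4, t_end = 200) {
  saddle <- unname(saddle)
  J <- grn_jacobian(saddle, network, params)
  ev <- eigen(J)
  unstable <- which(Re(ev$values) > 0)
  if (length(unstable) != 1L)
    stop("saddle must have exactly one unstable direction (has ",
         length(unstable), ")", call. = FALSE)
  v <- Re(ev$vectors[, unstable])
  v <- v / max(abs(v))
  half <- function(sign) {
    traj <- simulate_grn(network, params, pmax(saddle + sign * eps * v, 0),
                         t_end = t_end, n_out = 400)
    df <- data.frame(traj$states[, coords, drop = FALSE])
    names(df) <- coords
    attr(df, "endpoint") <- traj$states[nrow(traj$states), ]
    df
  }
  list(plus = half(1), minus = half(-1))
}

#' Write a landscape to plain-text files
#'
#' Matrices `counts`, `P` and `U` go to `<stem>.counts.tsv`,
#' `<stem>.P.tsv`, `<stem>.U.tsv`; metadata to `<stem>.meta.json`.
#'
#' @param grid a `grn_landscape`.
#' @param stem path stem for the output files.
#' @return `stem`, invisibly.
#' @export
write_landscape <- function(grid, stem) {
  wr <- function(m, suffix)
    utils::write.table(m, paste0(stem, ".", suffix, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  wr(grid$counts, "counts")
  wr(grid$P, "P")
  wr(grid$U, "U")
  meta <- grid$metadata
  meta$params <- unclass(meta$params)
  meta$coords <- grid$coords
  jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Plot a quasi-potential landscape
#'
#' `type = "top"` draws a filled top view (image) of U with basins
#' marked; `type = "surface"` a 3D perspective surface with elevation
#' U.
#'
#' @param x a `grn_landscape`.
#' @param type `"top"` or `"surface"`.
#' @param minima optional data frame from [locate_basins()] to mark.
#' @param ... passed to [graphics::image()] or [graphics::persp()].
#' @return Invisibly, `x`.
#' @export
plot.grn_landscape <- function(x, type = c("top", "surface"),
                               minima = NULL, ...) {
  type <- match.arg(type)
  pal <- grDevices::hcl.colors(64, "Blues 3")
  if (type == "top") {
    graphics::image(x$mids, x$mids, x$U, col = pal,
                    xlab = x$coords[1L], ylab = x$coords[2L], ...)
    if (!is.null(minima))
      graphics::points(minima[[x$coords[1L]]], minima[[x$coords[2L]]],
                       pch = 4, col = "red", lwd = 2)
  } else {
    graphics::persp(x$mids, x$mids, x$U, theta = 35, phi = 25,
                    xlab = x$coords[1L], ylab = x$coords[2L],
                    zlab = "U", col = "lightsteelblue",
                    border = NA, shade = 0.6, ...)
  }
  invisible(x)
}
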
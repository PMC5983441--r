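# Synthetic landscape grid with known minima, for unit-testing the
# basin detection independently of the ODE machinery.
synthetic_grid <- function(nb = 60, wells = list(c(15, 15), c(45, 40)),
                           weights = c(2e5, 1e5), noise_seed = 1) {
  set.seed(noise_seed)
  counts <- matrix(0, nb, nb)
  for (w in seq_along(wells)) {
    cx <- wells[[w]][1]; cy <- wells[[w]][2]
    for (i in max(1, cx - 6):min(nb, cx + 6))
      for (j in max(1, cy - 6):min(nb, cy + 6))
        counts[i, j] <- counts[i, j] +
          weights[w] * exp(-((i - cx)^2 + (j - cy)^2) / 6)
  }
  noise <- matrix(rpois(nb * nb, 0.2), nb, nb)
  counts <- round(counts) + noise
  # wells are visited by many trajectories, speckle by a single one
  traj_count <- (counts > 50) * 100 + (noise > 0) * 1
  P <- counts / sum(counts)
  U <- matrix(NA_real_, nb, nb)
  U[P > 0] <- -log(P[P > 0])
  cap <- max(U, na.rm = TRUE) + 1
  U[P == 0] <- cap
  structure(list(coords = c("p53", "ATM"),
                 breaks = seq(0, 3, length.out = nb + 1),
                 mids = (seq_len(nb) - 0.5) * 3 / nb,
                 counts = counts, traj_count = traj_count, P = P, U = U,
                 empty = P == 0, U_cap = cap,
                 metadata = list(n_traj = 1000, n_boxes = nb, x_max = 3)),
            class = "grn_landscape")
}

test_that("basin detection recovers planted wells and ignores speckle", {
  g <- synthetic_grid()
  m <- locate_basins(g)
  expect_identical(nrow(m), 2L)
  expect_identical(sort(m$ix), c(15L, 45L))
  # deeper (heavier) well ranks first
  expect_identical(m$ix[which.min(m$U)], 15L)
  # near-coincident minima merge into one
  g2 <- synthetic_grid(wells = list(c(30, 30), c(32, 31)),
                       weights = c(2e5, 1e5))
  expect_identical(nrow(locate_basins(g2)), 1L)
})

test_that("landscape probabilities are a proper distribution", {
  g <- estimate_landscape(canonical_network, grn_params(a = 0.5),
                          n_traj = 200, n_samples_per_traj = 100,
                          seed = 3)
  expect_equal(sum(g$P), 1)
  expect_true(all(g$counts == round(g$counts)))
  expect_identical(sum(g$counts), 200 * 100)
  vis <- !g$empty
  expect_equal(g$U[vis], -log(g$P[vis]))
  expect_true(all(g$U[g$empty] == g$U_cap))
  expect_error(estimate_landscape(canonical_network, canonical_params,
                                  coords = c("p53", "nosuch")),
               "must be nodes")
})

test_that("landscapes are reproducible under a fixed seed", {
  g1 <- estimate_landscape(canonical_network, canonical_params,
                           n_traj = 100, n_samples_per_traj = 50,
                           seed = 11)
  g2 <- estimate_landscape(canonical_network, canonical_params,
                           n_traj = 100, n_samples_per_traj = 50,
                           seed = 11)
  expect_identical(g1$counts, g2$counts)
})

test_that("U minima co-locate with the stable fixed points", {
  # a = 1.0: three true cell-fate attractors, no fold ghosts nearby
  p1 <- grn_params(a = 1)
  g <- estimate_landscape(canonical_network, p1, n_traj = 3000,
                          seed = 13)
  m <- locate_basins(g)
  expect_identical(nrow(m), 3L)
  refs <- rbind(fixed_point_from(low_start(), params = p1),
                fixed_point_from(intermediate_start(), params = p1),
                fixed_point_from(rep(2, 13), params = p1))
  width <- 3 / g$metadata$n_boxes
  for (i in seq_len(nrow(m))) {
    d <- apply(abs(cbind(refs[, "p53"] - m$p53[i],
                         refs[, "ATM"] - m$ATM[i])), 1, max)
    expect_lt(min(d), width)  # within one box of an attractor
  }
})

test_that("basin counts are stable when the trajectory count doubles", {
  g1 <- estimate_landscape(canonical_network, grn_params(a = 0.5),
                           n_traj = 1000, seed = 17)
  g2 <- estimate_landscape(canonical_network, grn_params(a = 0.5),
                           n_traj = 2000, seed = 17)
  m1 <- locate_basins(g1)
  m2 <- locate_basins(g2)
  expect_identical(nrow(m1), 1L)
  expect_identical(nrow(m2), 1L)
  expect_lte(max(abs(c(m1$ix - m2$ix, m1$iy - m2$iy))), 1)
})

test_that("ageing shifts the landscape from one basin to two", {
  g_young <- estimate_landscape(canonical_network, grn_params(a = 0.5),
                                n_traj = 1500, seed = 19)
  g_old <- estimate_landscape(canonical_network, grn_params(a = 1.5),
                              n_traj = 1500, seed = 19)
  m_young <- basin_depth_rank(g_young, locate_basins(g_young))
  m_old <- basin_depth_rank(g_old, locate_basins(g_old))
  expect_identical(nrow(m_young), 1L)
  expect_identical(m_young$phenotype, "homeostasis")
  expect_identical(nrow(m_old), 2L)
  expect_identical(m_old$phenotype[1], "senescence_or_apoptosis")
})

test_that("the p21-ATM projection shows the same ageing landscape", {
  g <- estimate_landscape(canonical_network, grn_params(a = 1.5),
                          coords = c("p21", "ATM"), n_traj = 1500,
                          seed = 23)
  m <- locate_basins(g)
  expect_identical(nrow(m), 2L)
  expect_gt(max(m$p21), 1)  # senescence basin sits at high p21
})

test_that("heteroclinic paths leave the saddle in both directions", {
  p1 <- grn_params(a = 1)
  x_h <- fixed_point_from(low_start(), params = p1)
  x_a <- fixed_point_from(intermediate_start(), params = p1)
  sad <- find_saddle(canonical_network, p1, x_h, x_a)
  paths <- saddle_path(canonical_network, p1, sad$state)
  e_plus <- attr(paths$plus, "endpoint")
  e_minus <- attr(paths$minus, "endpoint")
  ends <- sort(c(e_plus[["p53"]], e_minus[["p53"]]))
  expect_lt(abs(ends[1] - x_h[["p53"]]), 1e-3)
  expect_lt(abs(ends[2] - x_a[["p53"]]), 1e-3)
  # flipping the displacement sign swaps the two endpoints
  paths2 <- saddle_path(canonical_network, p1, sad$state, eps = -1e-4)
  expect_equal(attr(paths2$plus, "endpoint"), e_minus, tolerance = 1e-4)
  # an attractor is not a path-defining saddle
  expect_error(saddle_path(canonical_network, p1, x_h),
               "exactly one unstable direction")
})

test_that("landscape files round-trip through the writers", {
  g <- estimate_landscape(canonical_network, grn_params(a = 0.5),
                          n_traj = 50, n_samples_per_traj = 50,
                          seed = 29)
  stem <- file.path(withr::local_tempdir(), "ls")
  write_landscape(g, stem)
  U <- as.matrix(utils::read.table(paste0(stem, ".U.tsv")))
  expect_equal(unname(U), unname(g$U))
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$coords, c("p53", "ATM"))
  expect_identical(meta$n_traj, 50L)
})
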
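test_that("the analytic Jacobian matches finite differences", {
  set.seed(21)
  for (i in 1:5) {
    x <- runif(13, 0, 3)
    J <- grn_jacobian(x, canonical_network, canonical_params)
    h <- 1e-6
    fd <- vapply(1:13, function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- max(xm[j] - h, 0)
      (grn_rhs(xp, canonical_network, canonical_params) -
         grn_rhs(xm, canonical_network, canonical_params)) /
        (xp[j] - xm[j])
    }, numeric(13))
    expect_lt(max(abs(J - fd)), 1e-6)
  }
})

test_that("the Jacobian at the origin is pure degradation", {
  J <- grn_jacobian(rep(0, 13), canonical_network, canonical_params)
  expect_equal(unname(diag(J)), rep(-1, 13))
  expect_equal(max(abs(J - diag(diag(J)))), 0)
})

test_that("the Wip1 row has a single regulator entry", {
  set.seed(2)
  J <- grn_jacobian(runif(13, 0.2, 2), canonical_network,
                    canonical_params)
  off <- J["Wip1", setdiff(colnames(J), "Wip1")]
  expect_identical(names(off)[off != 0], "p53")
})

test_that("multistart finds a single attractor at low activation rate", {
  att <- find_attractors(canonical_network, grn_params(a = 0.5),
                         n_starts = 80, seed = 2)
  expect_identical(sum(att$stable), 1L)
  expect_lt(att$states[att$stable, "p53"], 0.3)
  expect_identical(att$n_unconverged, 0L)
})

test_that("reported attractors are genuine, stable and bounded", {
  att <- find_attractors(canonical_network, grn_params(a = 1.5),
                         n_starts = 120, seed = 4)
  expect_gte(nrow(att$states), 1)
  m <- ageingGRN:::network_matrices(canonical_network)
  bound <- (1.5 * rowSums(m$Mact) + 0.05 * rowSums(m$Minh)) / 1
  for (i in seq_len(nrow(att$states))) {
    res <- grn_rhs(att$states[i, ], canonical_network,
                   grn_params(a = 1.5))
    expect_lt(max(abs(res)), 1e-8)
    expect_true(all(att$states[i, ] <= bound + 1e-9))
  }
  expect_true(all(att$spectral_abscissa[att$stable] < 0))
  expect_equal(sum(att$basin_fraction, na.rm = TRUE), 1)
})

test_that("the attractor set saturates as starts double", {
  a1 <- find_attractors(canonical_network, grn_params(a = 1.5),
                        n_starts = 60, seed = 8)
  a2 <- find_attractors(canonical_network, grn_params(a = 1.5),
                        n_starts = 120, seed = 8)
  expect_identical(nrow(a1$states), nrow(a2$states))
  for (i in seq_len(nrow(a1$states)))
    expect_lt(min(apply(abs(sweep(a2$states, 2, a1$states[i, ])), 1,
                        max)), 1e-3)
})

test_that("cell fates collapse E2F-variant attractor pairs", {
  att <- find_attractors(canonical_network, grn_params(a = 1.5),
                         n_starts = 120, seed = 4)
  fates <- fate_census(att)
  expect_identical(nrow(fates), 1L)        # only senescence survives
  expect_identical(fates$phenotype, "senescence_or_apoptosis")
  expect_gte(sum(att$stable), nrow(fates)) # E2F variants are distinct states
})

test_that("phenotype labels partition the marker plane as specified", {
  th <- list(p53_low = 0.5, p53_high = 1.5, atm = 0.6)
  lab <- function(p53, atm)
    classify_phenotype(c(p53 = p53, ATM = atm), th)
  expect_identical(lab(0.1, 0.1), "homeostasis")
  expect_identical(lab(0.1, 1.5), "cancer")
  expect_identical(lab(1.0, 0.1), "cell_cycle_arrest")
  expect_identical(lab(2.0, 1.5), "senescence_or_apoptosis")
  expect_identical(lab(2.0, 0.1), "unclassified")
  expect_identical(lab(1.0, 1.5), "unclassified")
  expect_error(classify_phenotype(c(p53 = 1, ATM = 1),
    list(p53_low = 2, p53_high = 1, atm = 0.5)), "p53_low < p53_high")
})

test_that("default thresholds sit between the computed branch levels", {
  th <- phenotype_thresholds()
  low <- fixed_point_from(low_start())
  mid <- fixed_point_from(intermediate_start())
  high <- fixed_point_from(rep(2, 13))
  expect_true(low[["p53"]] < th$p53_low && th$p53_low < mid[["p53"]])
  expect_true(mid[["p53"]] < th$p53_high && th$p53_high < high[["p53"]])
  expect_true(mid[["ATM"]] < th$atm && th$atm < high[["ATM"]])
})

test_that("a saddle separates homeostasis from cell-cycle arrest", {
  p1 <- grn_params(a = 1)
  x_h <- fixed_point_from(low_start(), params = p1)
  x_a <- fixed_point_from(intermediate_start(), params = p1)
  sad <- find_saddle(canonical_network, p1, x_h, x_a)
  expect_lt(sad$residual, 1e-8)
  expect_identical(sad$n_unstable, 1L)
  expect_true(x_h[["p53"]] < sad$state[["p53"]] &&
                sad$state[["p53"]] < x_a[["p53"]])
})

test_that("the attractor table writes one row per fixed point", {
  att <- find_attractors(canonical_network, grn_params(a = 0.5),
                         n_starts = 40, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_attractors_csv(att, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_identical(nrow(back), nrow(att$states))
  expect_true(all(c("p53", "stable", "basin_fraction", "phenotype")
                  %in% names(back)))
})
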
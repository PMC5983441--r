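test_that("continuation refuses a start that is not a fixed point", {
  expect_error(continue_branch(canonical_network, canonical_params, "a",
                               1, rep(0.5, 13)), "not a fixed point")
})

test_that("branch points satisfy the Wip1 steady-state relation", {
  p03 <- grn_params(a = 0.3)
  x0 <- fixed_point_from(low_start(), params = p03)
  br <- continue_branch(canonical_network, canonical_params, "a", 0.3,
                        x0, direction = 1, step = 0.02,
                        bounds = c(0.3, 0.9))
  expect_gt(nrow(br), 10)
  for (i in seq_len(nrow(br)))
    expect_lt(abs(br$Wip1[i] -
                    br$param[i] * hill_activation(br$p53[i], 0.5, 4)),
              1e-8)
  expect_true(all(br$stable))
  expect_length(branch_folds(br), 0)  # no fold inside [0.3, 0.9]
})

test_that("the low-branch fold is step-size invariant", {
  p1 <- grn_params(a = 1)
  x0 <- fixed_point_from(low_start(), params = p1)
  br_a <- continue_branch(canonical_network, canonical_params, "a", 1,
                          x0, direction = 1, step = 0.01,
                          bounds = c(1, 1.6))
  br_b <- continue_branch(canonical_network, canonical_params, "a", 1,
                          x0, direction = 1, step = 0.005,
                          bounds = c(1, 1.6))
  f_a <- branch_folds(br_a)
  f_b <- branch_folds(br_b)
  expect_length(f_a, 1)
  expect_length(f_b, 1)
  expect_lt(abs(f_a - f_b), 1e-3)
})

test_that("the spectral gap closes as the fold is approached", {
  p1 <- grn_params(a = 1)
  x0 <- fixed_point_from(low_start(), params = p1)
  br <- continue_branch(canonical_network, canonical_params, "a", 1,
                        x0, direction = 1, step = 0.01,
                        bounds = c(1, 1.6), fold_tol = 1e-5)
  last <- as.numeric(br[nrow(br), canonical_network$nodes])
  p_last <- grn_params(a = br$param[nrow(br)])
  ev <- eigen(grn_jacobian(last, canonical_network, p_last),
              only.values = TRUE)$values
  expect_lt(min(abs(Re(ev))), 1e-2)
})

test_that("stable branch points coincide with multistart attractors", {
  p <- grn_params(a = 0.5)
  x0 <- fixed_point_from(low_start(), params = p)
  br <- continue_branch(canonical_network, canonical_params, "a", 0.5,
                        x0, direction = 1, step = 0.05,
                        bounds = c(0.5, 0.7))
  att <- find_attractors(canonical_network, grn_params(a = 0.7),
                         n_starts = 60, seed = 6)
  i <- which(abs(br$param - 0.7) < 1e-9)
  expect_length(i, 1)
  d <- apply(abs(sweep(att$states, 2,
                       as.numeric(br[i, canonical_network$nodes]))), 1,
             max)
  expect_lt(min(d), 1e-3)
})

test_that("hysteresis sweeps disagree exactly between the folds", {
  # the ramp must step finely past the first fold: overshooting it lets
  # ATM slip past its recapture threshold and the arrest step is skipped
  vals <- seq(0.4, 2, by = 0.02)
  hs <- hysteresis_sweep(canonical_network, canonical_params, "a",
                         vals, rev(vals))
  up <- hs$up$p53
  down <- rev(hs$down$p53)
  # folds at 0.747 and 1.455: strictly between them the sweeps disagree
  between <- vals > 0.76 & vals < 1.44
  outside <- vals < 0.74 | vals > 1.46
  expect_true(all(abs(up[between] - down[between]) > 0.1))
  expect_true(all(abs(up[outside] - down[outside]) < 1e-5))
  # two upward jumps (p53 ON at 1.16 and 1.46), one downward (OFF at 0.74)
  expect_equal(vals[which(diff(up) > 0.3) + 1L], c(1.16, 1.46))
  expect_identical(sum(diff(rev(down)) < -0.3), 1L)
})

test_that("the two-parameter scan counts mono- and multistability", {
  rm_ <- scan_two_parameters(canonical_network, canonical_params,
                             a_values = c(0.3, 2.0),
                             b_values = c(0.05), n_starts = 60,
                             seed = 2)
  expect_identical(unname(rm_$n_fates[, 1]), c(1L, 1L))
  expect_true(all(rm_$n_states >= 1))
  # at a = 2 the single fate splits into quiescent/proliferative states
  expect_identical(unname(rm_$n_states[2, 1]), 2L)
})

test_that("growth signals gate cell-cycle activation with two folds", {
  cc <- cell_cycle_bifurcation(canonical_network, canonical_params,
                               readout = "E2F", gs_range = c(0, 0.8),
                               step = 0.005)
  expect_length(cc$folds, 2)
  expect_true(all(cc$folds > 0 & cc$folds < 0.8))
  # the E2F-off branch (from the zero state) dies at the first fold
  br1 <- cc$branches[[1]]
  expect_lt(max(br1$E2F), 0.5)
  # CycD rises monotonically with growth signals along every branch
  for (br in cc$branches) {
    o <- order(br$param)
    expect_true(all(diff(br$CycD[o]) > -1e-9))
  }
  expect_error(cell_cycle_bifurcation(canonical_network,
    canonical_params, readout = "nosuch"), "not a node")
})

test_that("the zero-growth-signal branch value is the GS-free fixed point", {
  cc <- cell_cycle_bifurcation(canonical_network, canonical_params,
                               readout = "E2F", gs_range = c(0, 0.3),
                               step = 0.01)
  br1 <- cc$branches[[1]]
  i0 <- which(br1$param == 0)
  expect_length(i0, 1)
  p0 <- set_param(canonical_params, "GS", 0)
  ref <- fixed_point_from(low_start(), params = p0)
  expect_lt(max(abs(as.numeric(br1[i0, canonical_network$nodes]) - ref)),
            1e-8)
})

test_that("branch and region writers emit readable files", {
  p <- grn_params(a = 0.3)
  x0 <- fixed_point_from(low_start(), params = p)
  br <- continue_branch(canonical_network, canonical_params, "a", 0.3,
                        x0, direction = 1, step = 0.05,
                        bounds = c(0.3, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_branch_csv(br, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_identical(nrow(back), nrow(br))
  sidecar <- jsonlite::read_json(paste0(f, ".folds.json"),
                                 simplifyVector = TRUE)
  expect_identical(sidecar$param_name, "a")
  withr::defer(unlink(paste0(f, ".folds.json")))
})
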
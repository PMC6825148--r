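test_that("activation function follows the three-branch definition and is continuous", {
  expect_identical(activation_phi(-2), 0)
  expect_identical(activation_phi(0.5), 0.25)
  expect_identical(activation_phi(1), 1)
  expect_equal(activation_phi(3), sqrt(4 * 3 - 3))  # = 3, direct evaluation
  # continuity at both knots
  eps <- 1e-8
  expect_equal(activation_phi(0 + eps), activation_phi(0 - eps), tolerance = 1e-7)
  expect_equal(activation_phi(1 + eps), activation_phi(1 - eps), tolerance = 1e-7)
  expect_error(activation_phi(c(1, NA)), "non-finite")
  expect_error(activation_phi(Inf), "non-finite")
})

test_that("ring weight matrix has local excitation, global inhibition, symmetry", {
  cfg <- bump_config(excitation_radius = 2)
  W <- build_bump_weights(cfg)
  expect_equal(dim(W), c(80, 80))
  # 5 excitatory entries per row: self + 2 on each side
  expect_true(all(rowSums(W > 0) == 5))
  expect_true(all(W[W < 0] == -cfg$inhibition_weight))
  expect_identical(W, t(W))
  # wrap-around: first and last units are ring neighbors
  expect_equal(W[1, 80], cfg$excitation_weight)
  cfg0 <- bump_config(excitation_weight = 0, inhibition_weight = 0)
  expect_true(all(build_bump_weights(cfg0) == 0))
  expect_error(build_bump_weights(bump_config(excitation_radius = 40)),
               "excitation_radius")
})

test_that("bump simulation is seeded, reproducible, and respects the task structure", {
  cfg <- small_bump_cfg()
  tl <- task_timeline()
  expect_error(simulate_bump_attractor(cfg, tl, 1), "seeded")
  x1 <- simulate_bump_attractor(cfg, tl, 2, seed = 5)
  x2 <- simulate_bump_attractor(cfg, tl, 2, seed = 5)
  expect_identical(x1$rates, x2$rates)
  expect_s3_class(x1, "population_tensor")
  # conditions: 4 targets x 3 distractors x 2 trials
  expect_equal(dim(x1$rates)[3], 4 * 3 * 2)
  expect_true(all(x1$trial_table$distractor_loc != x1$trial_table$target_loc))
  expect_true(all(x1$rates >= 0))
})

test_that("noise-free dynamics with no distractor-period input reach a fixed point", {
  cfg <- bump_config(noise_sd = 0, distractor_amplitude = 0,
                     nonmemory_amplitude = 0)
  tl <- task_timeline()
  x <- simulate_bump_attractor(cfg, tl, 1, seed = 3)
  ta <- x$time_axis
  end_d1 <- which(ta == tl$delay1[2] - tl$step_ms)
  end_d2 <- which(ta == tl$delay2[2] - tl$step_ms)
  # autonomous contraction toward a fixed point: successive-step change at the
  # end of Delay 2 is tiny, and the Delay-1 and Delay-2 states agree closely
  step_change <- sqrt(sum((x$rates[, end_d2, 1] - x$rates[, end_d2 - 1, 1])^2))
  expect_lt(step_change, 0.05)
  rel <- sqrt(sum((x$rates[, end_d1, 1] - x$rates[, end_d2, 1])^2)) /
    sqrt(sum(x$rates[, end_d1, 1]^2))
  expect_lt(rel, 0.05)
})

test_that("the target bump persists through Delay 2 above other blocks", {
  cfg <- bump_config()
  tl <- task_timeline()
  x <- simulate_bump_attractor(cfg, tl, 2, seed = 11)
  ta <- x$time_axis
  d2 <- which(ta >= 1800 & ta < 2300)
  nm <- x$meta$nonmemory_ids
  tt <- x$trial_table
  excess <- vapply(seq_len(nrow(tt)), function(tr) {
    blk <- (tt$target_loc[tr] - 1) * 10 + 1:10
    others <- setdiff(seq_len(80), c(blk, nm))
    mean(x$rates[blk, d2, tr]) - mean(x$rates[others, d2, tr])
  }, numeric(1))
  expect_gt(mean(excess), 0)
})

test_that("default weights satisfy the calibration contracts", {
  cal <- check_bump_calibration(bump_config(), task_timeline(), seed = 1,
                                n_trials = 5)
  expect_true(cal$no_spontaneous_bumps)
  expect_true(cal$bump_persists)
})

test_that("linear model keeps stable-eigenvector content constant and decays the rest", {
  cfg <- linear_config(n_units = 20L, n_locations = 8L, noise_sd = 0,
                       distractor_amplitude = 0, nonmemory_amplitude = 0)
  tl <- task_timeline()
  x <- simulate_linear_model(cfg, tl, 1, seed = 9)
  # reconstruct the recurrent system exactly as the simulator drew it
  rec <- morphspace:::with_local_seed(9, morphspace:::build_linear_recurrent(cfg))
  ta <- x$time_axis
  end_d1 <- which(ta == tl$delay1[2] - tl$step_ms)
  end_d2 <- which(ta == tl$delay2[2] - tl$step_ms)
  Qinv <- solve(rec$Q)
  tr1 <- which(x$trial_table$target_loc == 1)[1]
  c_d1 <- (Qinv %*% x$rates[, end_d1, tr1])[1]   # target-1 eigencoordinate
  c_d2 <- (Qinv %*% x$rates[, end_d2, tr1])[1]
  expect_equal(c_d1, c_d2, tolerance = 1e-8)     # eigenvalue exactly 1

  # a state seeded on a decaying eigenvector decays as lambda^t
  lam <- rec$lambda[15]
  v <- rec$Q[, 15]
  r <- v
  for (k in 1:6) r <- rec$W_rec %*% r
  expect_equal(as.numeric(r), as.numeric(lam^6 * v), tolerance = 1e-8)
})

test_that("eigenvalues above 1 are rejected as unstable", {
  expect_error(linear_config(eigenvalue_range_unstable = c(0.5, 1.2)),
               "unstable")
})

test_that("error-trial scenario flags and degrades the requested fraction", {
  cfg <- small_bump_cfg()
  x <- simulate_scenario(cfg, "error_trials",
                         params = list(error_fraction = 0.5, degradation = 0.3),
                         seed = 4, n_trials_per_condition = 4L)
  tt <- x$trial_table
  expect_gt(sum(!tt$correct), 0)
  expect_gt(sum(tt$correct), 0)
  # degraded target input -> weaker target-block activity at end of Delay 1
  ta <- x$time_axis
  d1 <- which(ta >= 800 & ta < 1300)
  blk_rate <- vapply(seq_len(nrow(tt)), function(tr) {
    blk <- (tt$target_loc[tr] - 1) * cfg$units_per_location +
      seq_len(cfg$units_per_location)
    mean(x$rates[blk, d1, tr])
  }, numeric(1))
  expect_gt(mean(blk_rate[tt$correct]), mean(blk_rate[!tt$correct]))
  # identity case: no degradation -> error trials match correct statistics
  x0 <- simulate_scenario(cfg, "error_trials",
                          params = list(error_fraction = 0.5, degradation = 1),
                          seed = 4, n_trials_per_condition = 4L)
  blk0 <- vapply(seq_len(nrow(x0$trial_table)), function(tr) {
    blk <- (x0$trial_table$target_loc[tr] - 1) * cfg$units_per_location +
      seq_len(cfg$units_per_location)
    mean(x0$rates[blk, d1, tr])
  }, numeric(1))
  expect_equal(mean(blk0[x0$trial_table$correct]),
               mean(blk0[!x0$trial_table$correct]), tolerance = 0.1)
  expect_error(simulate_scenario(cfg, "not_a_scenario", seed = 1), "arg")
})

test_that("two-distractor scenarios gate the non-memory input as specified", {
  cfg <- small_bump_cfg()
  x_stim <- simulate_scenario(cfg, "two_distractors_stimulus_triggered",
                              seed = 6, n_trials_per_condition = 2L)
  x_prox <- simulate_scenario(cfg, "two_distractors_proximity_triggered",
                              seed = 6, n_trials_per_condition = 2L)
  nm <- x_stim$meta$nonmemory_ids
  ta <- x_stim$time_axis
  w1 <- which(ta >= 1300 & ta < 1600)   # first distractor
  w2 <- which(ta >= 2600 & ta < 2900)   # second distractor
  nm_rate <- function(x, w) mean(x$rates[nm, w, ])
  # stimulus-triggered: non-memory drive at both distractors
  expect_gt(nm_rate(x_stim, w1), 1)
  expect_gt(nm_rate(x_stim, w2), 1)
  # proximity-triggered: drive only at the final distractor (baseline overlap
  # with active location bumps keeps the first-window rate nonzero)
  expect_lt(nm_rate(x_prox, w1), nm_rate(x_prox, w2) / 1.5)
  expect_lt(nm_rate(x_prox, w1), nm_rate(x_stim, w1) / 1.5)
  expect_gt(nm_rate(x_prox, w2), 1)
  expect_equal(max(x_stim$time_axis) + x_stim$bin_ms, 3900)
})

test_that("parameter sweeps return one summary row per grid point", {
  cfg <- small_bump_cfg()
  sw <- simulate_scenario(cfg, "nonmemory_ns_sweep",
                          params = list(values = cbind(n = c(2, 4), s = c(5, 2)),
                                        n_trials_per_condition = 2L,
                                        n_responses = 10L, n_resamples = 10L),
                          seed = 13)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("n", "s", "lp11", "lp12", "lp11_minus_lp12") %in% names(sw)))
  expect_true(all(is.finite(sw$lp11_minus_lp12)))
})

test_that("timeline validation enforces contiguity and step divisibility", {
  expect_error(task_timeline(delay1 = c(350, 1300)), "contiguous")
  expect_error(task_timeline(step_ms = 70), "divide")
  tl <- task_timeline()
  expect_equal(length(tl$time_axis), 58L)
})

test_that("population tensors round-trip through the array container", {
  x <- make_tensor(array(runif(4 * 6 * 3), dim = c(4, 6, 3)))
  path <- file.path(tempdir(), "tensor_roundtrip.rds")
  write_population_tensor(x, path)
  y <- read_population_tensor(path)
  expect_equal(y$rates, x$rates)
  expect_equal(y$trial_table$target_loc, x$trial_table$target_loc)
  unlink(c(path, sub("\\.rds$", "_trials.csv", path)))
})
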
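test_that("subspace cost equals the hand-computed Frobenius combination", {
  set.seed(1)
  D1 <- matrix(rnorm(12), 3, 4); D2 <- matrix(rnorm(12), 3, 4)
  dm <- make_dm(D1, D2, labels = rep(1:2, each = 2))
  U <- matrix(rnorm(6), 2, 3)
  beta <- 0.37
  oracle <- frob_oracle(U %*% (D1 - D2)) -
    (beta / 2) * (frob_oracle(U %*% dm$D1_av) + frob_oracle(U %*% dm$D2_av))
  expect_equal(subspace_cost(U, dm, beta), oracle, tolerance = 1e-12)
  expect_identical(subspace_cost(matrix(0, 2, 3), dm, beta), 0)
  # D1 = D2: first term vanishes and the two centered terms coincide
  dm_eq <- make_dm(D1, D1, labels = rep(1:2, each = 2))
  expect_equal(subspace_cost(U, dm_eq, beta),
               -beta * frob_oracle(U %*% dm_eq$D1_av), tolerance = 1e-12)
  expect_error(subspace_cost(matrix(0, 2, 5), dm), "conformable")
})

test_that("cost is positively homogeneous of degree 1", {
  set.seed(2)
  dm <- make_dm(matrix(rnorm(40), 5, 8), matrix(rnorm(40), 5, 8),
                labels = rep(1:4, each = 2))
  U <- matrix(rnorm(15), 3, 5)
  for (c_scale in c(0.25, 2, 17)) {
    expect_equal(subspace_cost(c_scale * U, dm, 0.1),
                 c_scale * subspace_cost(U, dm, 0.1), tolerance = 1e-10)
  }
})

test_that("analytic gradient matches finite differences", {
  set.seed(3)
  dm <- make_dm(matrix(rnorm(30), 5, 6), matrix(rnorm(30), 5, 6),
                labels = rep(1:3, each = 2))
  U <- matrix(rnorm(10), 2, 5)
  G <- morphspace:::subspace_cost_grad(U, dm, 0.1)
  eps <- 1e-6
  for (k in sample(length(U), 5)) {
    Up <- U; Up[k] <- Up[k] + eps
    Um <- U; Um[k] <- Um[k] - eps
    fd <- (subspace_cost(Up, dm, 0.1) - subspace_cost(Um, dm, 0.1)) / (2 * eps)
    expect_equal(G[k], fd, tolerance = 1e-5)
  }
})

test_that("unconstrained optimizer rides an information-rich morph-free ray", {
  # construct data whose morph is rank-1 and orthogonal to the memory
  # structure: a direction exists with zero morph and full information
  set.seed(4)
  n <- 10
  mem <- matrix(0, n, 8)
  mem[1:4, ] <- matrix(rnorm(32, sd = 3), 4, 8)    # memory in dims 1-4
  common <- matrix(0, n, 8)
  common[n, ] <- 5                                  # morph purely in dim n
  D1 <- mem
  D2 <- mem + common
  dm <- make_dm(D1, D2, labels = rep(1:4, each = 2))
  m <- optimize_subspace(dm, beta = 0.1, u_dim = 3, seed = 5, n_starts = 3)
  expect_lt(m$cost, 0)    # found a negative-cost (information > morph) map
  # the found subspace nearly annihilates the morph direction relative to info
  ratio <- morphspace:::frobenius(m$U %*% (D1 - D2)) /
    morphspace:::frobenius(m$U %*% dm$D1_av)
  expect_lt(ratio, 0.05)
  # best-so-far cost trace is non-increasing
  expect_true(all(diff(m$cost_trace) <= 1e-9))
})

test_that("orthonormal mode returns an orthonormal map with decreasing cost", {
  set.seed(5)
  dm <- make_dm(matrix(rnorm(70, sd = 2), 7, 10),
                matrix(rnorm(70, sd = 2), 7, 10),
                labels = rep(1:5, each = 2))
  m <- optimize_subspace(dm, u_dim = 3, seed = 6, n_starts = 2,
                         constraint = "orthonormal")
  expect_lt(max(abs(m$U %*% t(m$U) - diag(3))), 1e-10)
  expect_true(all(diff(m$cost_trace) <= 1e-9))
  expect_error(optimize_subspace(dm, u_dim = 7, seed = 1), "u_dim")
})

test_that("projection matches brute-force multiplication and shape contracts", {
  set.seed(7)
  U <- matrix(rnorm(8 * 58), 8, 58)
  X <- matrix(rnorm(58 * 350), 58, 350)
  P <- project_subspace(list(U = U), X)
  expect_equal(dim(P), c(8, 350))
  # naive row-by-column oracle on a few entries
  for (k in 1:5) {
    i <- sample(8, 1); j <- sample(350, 1)
    expect_equal(P[i, j], sum(U[i, ] * X[, j]), tolerance = 1e-12)
  }
  U_id <- diag(58)[1:8, ]
  expect_equal(project_subspace(list(U = U_id), X), X[1:8, ])
  expect_identical(project_subspace(list(U = U), matrix(0, 58, 4)),
                   matrix(0, 8, 4))
  expect_error(project_subspace(list(U = U), matrix(0, 10, 4)), "mismatch")
})

test_that("null basis is orthonormal, annihilated, and correctly sized", {
  set.seed(8)
  U <- matrix(rnorm(8 * 58), 8, 58)
  V <- null_space_basis(list(U = U))
  expect_equal(dim(V), c(50, 58))
  expect_lt(max(abs(V %*% t(U))), 1e-8)
  expect_lt(max(abs(V %*% t(V) - diag(50))), 1e-8)
  # identity-rows map: null space spans the remaining coordinates
  U_id <- diag(58)[1:8, ]
  V_id <- null_space_basis(list(U = U_id))
  expect_lt(max(abs(V_id[, 1:8])), 1e-10)
  # rank-deficient map enlarges the null space with a warning
  U_def <- rbind(U[1:7, ], U[7, ])
  expect_warning(V_def <- null_space_basis(list(U = U_def)), "rank deficient")
  expect_equal(nrow(V_def), 51L)
})

test_that("neuron contributions are normalized per-neuron weights", {
  set.seed(9)
  fs <- list(loadings = matrix(rnorm(58 * 244), 58, 244))
  U <- matrix(rnorm(8 * 58), 8, 58)
  w <- neuron_contributions(list(U = U), fs)
  expect_length(w, 244)
  expect_true(all(w >= 0 & w <= 1))
  # normalization: the largest entrywise weight maps to exactly 1
  W <- abs(U %*% fs$loadings)
  expect_equal(max(W / max(W)), 1)
  expect_error(neuron_contributions(list(U = matrix(0, 8, 58)), fs),
               "degenerate")
})

test_that("subspace variance curve is cumulative and shape-checked", {
  set.seed(10)
  dm <- make_dm(matrix(rnorm(58 * 350), 58, 350),
                matrix(rnorm(58 * 350), 58, 350),
                labels = rep(1:7, each = 50))
  m <- list(U = matrix(rnorm(8 * 58), 8, 58))
  curve <- subspace_variance_curve(m, dm)    # decomposition of an 8 x 700 matrix
  expect_length(curve, 8)
  expect_true(all(diff(curve) >= -1e-12))
  expect_equal(curve[8], 1)
  # projections on a line: first component carries everything
  v <- matrix(rnorm(58), 58, 1)
  dm_line <- make_dm(v %*% t(seq_len(6)), v %*% t(seq(2, 12, 2)),
                     labels = rep(1:3, each = 2))
  curve_line <- subspace_variance_curve(list(U = matrix(rnorm(2 * 58), 2, 58)),
                                        dm_line)
  expect_equal(curve_line[1], 1, tolerance = 1e-10)
})

test_that("label shuffling prefers derangements and is deterministic", {
  set.seed(11)
  dm <- make_dm(matrix(rnorm(5 * 12), 5, 12), matrix(rnorm(5 * 12), 5, 12),
                labels = rep(1:4, each = 3))
  s1 <- shuffle_delay2_labels(dm, seed = 13)
  s2 <- shuffle_delay2_labels(dm, seed = 13)
  expect_identical(s1$D2, s2$D2)
  perm <- attr(s1, "permutation")
  expect_true(all(perm != 1:4))            # derangement when alternatives exist
  expect_identical(s1$D1, dm$D1)           # Delay 1 untouched
  expect_false(identical(s1$D2, dm$D2))
  expect_lt(max(abs(rowSums(s1$D2_av))), 1e-10)   # D2_av recomputed
  dm1 <- make_dm(matrix(1, 2, 2), matrix(2, 2, 2), labels = c(1, 1))
  expect_error(shuffle_delay2_labels(dm1, seed = 1), "2 locations")
})

test_that("baseline subspaces obey the same projection contract", {
  pp <- make_gauss_pp(n_dims = 8, locations = 1:5, n_per = 12, seed = 14)
  b1 <- baseline_subspace(pp, "time_averaged_pca", u_dim = 3)
  expect_equal(dim(b1$U), c(3, 8))
  expect_lt(max(abs(b1$U %*% t(b1$U) - diag(3))), 1e-8)
  b2 <- baseline_subspace(pp, "lda", u_dim = 3)
  expect_equal(dim(b2$U), c(3, 8))
  # stationary code: the mnemonic-subspace projection decodes both delays
  ps <- project_tensor(pp, b1, "baseline")
  ct <- cross_temporal_decode(ps, train_window = list(c(800, 1300), c(1800, 2300)),
                              n_resamples = 30, seed = 15)
  lp <- lp_statistics(ct)
  expect_gt(mean(lp$lp11), 0.9)
  expect_lt(abs(mean(lp$diff_11_12)), 0.05)
  expect_error(baseline_subspace(pp, "lda", u_dim = 5), "n_locations - 1")
})

test_that("held-out locations inherit time-invariance on stationary data", {
  pp <- make_gauss_pp(n_dims = 8, locations = 1:6, n_per = 12, seed = 16)
  dm <- build_delay_matrices(pp)
  res <- heldout_location_generalization(pp, dm, train_locations = 1:4,
                                         u_dim = 3, n_starts = 2,
                                         n_resamples = 30, seed = 17)
  expect_equal(res$heldout_locations, 5:6)
  expect_lt(abs(mean(res$lp$diff_11_12)), 0.05)
  expect_error(heldout_location_generalization(pp, dm, train_locations = 1:6,
                                               seed = 1), "empty")
  expect_error(heldout_location_generalization(pp, dm, train_locations = 1,
                                               seed = 1), "2 training")
})
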
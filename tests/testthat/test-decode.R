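test_that("decoder hits ceiling on separated stationary classes and chance on shuffled labels", {
  pp <- make_gauss_pp(n_dims = 5, locations = 1:4, n_per = 15,
                      separation = 4, seed = 21)
  ct <- cross_temporal_decode(pp, train_window = list(c(800, 1300), c(1800, 2300)),
                              n_resamples = 25, seed = 22)
  expect_true(all(ct$accuracy > 0.95))
  expect_equal(ct$chance, 0.25)
  # shuffled labels: every cell near chance, the average tightly so (a fixed
  # label shuffle leaves a small systematic cross-validation bias, so the
  # per-cell band is wider than the pure binomial one)
  set.seed(23)
  pp_shuf <- make_gauss_pp(n_dims = 5, locations = 1:4, n_per = 40,
                           separation = 4, seed = 21)
  pp_shuf$labels <- sample(pp_shuf$labels)
  ct_s <- cross_temporal_decode(pp_shuf, train_window = c(800, 1300),
                                n_resamples = 50, seed = 24)
  expect_true(all(abs(ct_s$accuracy - 0.25) < 0.1))
  expect_lt(abs(mean(ct_s$accuracy) - 0.25), 0.04)
})

test_that("in-package discriminant agrees with the reference implementation", {
  set.seed(25)
  n <- 120; p <- 4
  y <- rep(1:3, each = n / 3)
  X <- matrix(rnorm(n * p), n, p) + 2 * outer(y, seq_len(p), "*") / p
  fit <- morphspace:::lda_fit(X, y, shrinkage = "none")
  pred <- fit$classes[morphspace:::lda_predict(fit, X)]
  ref <- MASS::lda(X, grouping = factor(y))
  pred_ref <- as.integer(as.character(predict(ref, X)$class))
  expect_gt(mean(pred == pred_ref), 0.99)
})

test_that("LP statistics separate stationary from morphing codes", {
  # stationary: both paired differences center on zero
  pp <- make_gauss_pp(n_dims = 5, locations = 1:4, n_per = 15, seed = 26)
  ct <- cross_temporal_decode(pp, train_window = list(c(800, 1300), c(1800, 2300)),
                              n_resamples = 40, seed = 27)
  lp <- lp_statistics(ct)
  expect_lt(abs(mean(lp$diff_11_12)), 0.03)
  expect_lt(abs(mean(lp$diff_22_21)), 0.03)
  # location-dependent displacement after the distractor: morphing appears
  set.seed(28)
  shifts <- matrix(rnorm(5 * 4, sd = 6), 5, 4)
  pp_m <- make_gauss_pp(n_dims = 5, locations = 1:4, n_per = 15,
                        shift = shifts, seed = 26)
  ct_m <- cross_temporal_decode(pp_m, train_window = list(c(800, 1300), c(1800, 2300)),
                                n_resamples = 40, seed = 27)
  lp_m <- lp_statistics(ct_m)
  expect_gt(quantile(lp_m$diff_11_12, 0.025), 0)
  expect_error(lp_statistics(ct, d2_window = c(5000, 6000)), "window")
})

test_that("decoding accuracy is invariant to invertible subspace re-parameterization", {
  pp <- make_gauss_pp(n_dims = 6, locations = 1:4, n_per = 12,
                      separation = 1.2, noise = 0.8, seed = 29)
  set.seed(30)
  M <- matrix(rnorm(36), 6, 6) + 3 * diag(6)   # well-conditioned invertible map
  pp_t <- pp
  d <- dim(pp$z)
  pp_t$z <- array(M %*% matrix(pp$z, nrow = 6), dim = d)
  args <- list(train_window = c(800, 1300), n_resamples = 15,
               shrinkage = "none", seed = 31)
  a1 <- do.call(cross_temporal_decode, c(list(pp), args))$accuracy
  a2 <- do.call(cross_temporal_decode, c(list(pp_t), args))$accuracy
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("error-location filter applies the per-session threshold", {
  tt <- data.frame(session = 1L, target_loc = rep(c("A", "B"), c(12, 10)),
                   correct = c(rep(FALSE, 7), rep(TRUE, 5),
                               rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(filter_error_locations(tt), "A")
  tt2 <- rbind(data.frame(session = 1L, target_loc = rep(c("A", "B"), c(6, 6)),
                          correct = FALSE),
               data.frame(session = 2L, target_loc = rep(c("A", "B"), c(6, 3)),
                          correct = FALSE))
  expect_equal(filter_error_locations(tt2), "A")
  tt3 <- data.frame(session = 1L, target_loc = rep(1:3, each = 6), correct = FALSE)
  expect_equal(filter_error_locations(tt3), 1:3)
  tt4 <- data.frame(session = 1L, target_loc = 1:3, correct = TRUE)
  expect_message(out <- filter_error_locations(tt4), "no analyzable")
  expect_length(out, 0)
})

test_that("error-trial decoding localizes degradation to the targeted space", {
  pp <- make_gauss_pp(n_dims = 6, locations = 1:4, n_per = 20,
                      separation = 3, seed = 32)
  set.seed(33)
  U <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))    # 2-dim "subspace"
  map <- structure(list(U = t(U), u_dim = 2L), class = "subspace_map")
  V <- null_space_basis(map)
  # identical error trials: differences concentrate near zero in every space
  perf0 <- error_trial_performance(pp, pp, map, n_resamples = 20, seed = 34)
  for (sp in c("full", "subspace", "null"))
    expect_lt(abs(mean(perf0[[sp]]$diff)), 0.05)
  # degradation confined to the null space: null-space drop exceeds
  # subspace drop, and the subspace read-out is untouched
  pp_err <- pp
  d <- dim(pp$z)
  set.seed(35)
  noise_null <- t(V) %*% matrix(rnorm(nrow(V) * d[2] * d[3], sd = 6), nrow(V))
  pp_err$z <- pp$z + array(noise_null, dim = d)
  perf <- error_trial_performance(pp, pp_err, map, n_resamples = 20, seed = 34)
  expect_gt(mean(perf$null$diff), mean(perf$subspace$diff) + 0.05)
  expect_lt(abs(mean(perf$subspace$diff)), 0.05)
})

test_that("data confined to the subspace decodes at chance in the null space", {
  pp <- make_gauss_pp(n_dims = 6, locations = 1:4, n_per = 15,
                      separation = 3, noise = 0, seed = 36)
  set.seed(37)
  U <- t(qr.Q(qr(matrix(rnorm(6 * 2), 6, 2))))
  map <- structure(list(U = U, u_dim = 2L), class = "subspace_map")
  # keep only the subspace component of the signal, add isotropic noise
  d <- dim(pp$z)
  flat <- matrix(pp$z, nrow = 6)
  pp$z <- array(t(U) %*% (U %*% flat), dim = d) +
    array(rnorm(prod(d), sd = 0.3), dim = d)
  V <- null_space_basis(map)
  pn <- project_tensor(pp, V, "null")
  ct <- cross_temporal_decode(pn, train_window = c(800, 1300),
                              n_resamples = 40, seed = 38)
  expect_lt(max(abs(ct$accuracy - ct$chance)), 0.12)
})
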
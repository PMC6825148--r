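#' Linear eigenvector-subspace model configuration
#'
#' The comparison model: linear dynamics `r[t+1] = W_rec r[t] + W_in I[t] +
#' noise` with `W_rec = Q Lambda Q^-1`, where the first
#' `n_stable_eigenvalues` eigenvalues equal exactly 1 (stable, non-decaying
#' directions) and the remainder are drawn uniformly from (0, 1) (geometric
#' decay). The eight target inputs and the single non-memory input are each
#' assigned one stable eigenvector, so everything delivered along them
#' persists without decay.
#'
#' @param n_units Number of units (default 80).
#' @param n_locations Number of stimulus locations (default 8).
#' @param n_stable_eigenvalues Number of unit eigenvalues; must be at least
#'   `n_locations + 1` (default 9: 8 targets + 1 non-memory direction).
#' @param target_amplitude,distractor_amplitude,nonmemory_amplitude Input
#'   strengths, as in [bump_config()].
#' @param noise_sd Per-step Gaussian noise sd (default 0.1).
#' @param eigenvalue_range_unstable Interval from which the non-stable
#'   eigenvalues are drawn uniformly; must lie within \[0, 1\] (any requested
#'   eigenvalue magnitude above 1 is rejected as unstable dynamics).
#' @param max_condition Maximum acceptable condition number of `Q`; `Q` is
#'   re-drawn until below this bound (default 1e6).
#' @return An object of class `linear_config`.
#' @export
linear_config <- function(n_units = 80L,
                          n_locations = 8L,
                          n_stable_eigenvalues = 9L,
                          target_amplitude = 1,
                          distractor_amplitude = 0.2 * target_amplitude,
                          nonmemory_amplitude = 5,
                          noise_sd = 0.1,
                          eigenvalue_range_unstable = c(0, 1),
                          max_condition = 1e6) {
  if (n_stable_eigenvalues < n_locations + 1L)
    stop("need at least n_locations + 1 stable eigenvectors", call. = FALSE)
  if (n_stable_eigenvalues > n_units)
    stop("more stable eigenvalues than units", call. = FALSE)
  if (min(eigenvalue_range_unstable) < 0 || max(eigenvalue_range_unstable) > 1)
    stop("eigenvalues with magnitude above 1 give unstable dynamics; ",
         "eigenvalue_range_unstable must lie within [0, 1]", call. = FALSE)
  structure(list(n_units = as.integer(n_units),
                 n_locations = as.integer(n_locations),
                 n_stable_eigenvalues = as.integer(n_stable_eigenvalues),
                 target_amplitude = target_amplitude,
                 distractor_amplitude = distractor_amplitude,
                 nonmemory_amplitude = nonmemory_amplitude,
                 noise_sd = noise_sd,
                 eigenvalue_range_unstable = eigenvalue_range_unstable,
                 max_condition = max_condition),
            class = "linear_config")
}

# Draw Q (unit-norm columns) and assemble W_rec = Q Lambda Q^-1. Eigenvalues
# beyond the stable set are uniform in (0, 1); any requested |eigenvalue| > 1
# is rejected upstream by construction.
build_linear_recurrent <- function(cfg) {
  n <- cfg$n_units
  repeat {
    Q <- matrix(stats::rnorm(n * n), n, n)
    Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
    if (kappa(Q, exact = FALSE) < cfg$max_condition) break
  }
  lambda <- c(rep(1, cfg$n_stable_eigenvalues),
              stats::runif(n - cfg$n_stable_eigenvalues,
                           cfg$eigenvalue_range_unstable[1],
                           cfg$eigenvalue_range_unstable[2]))
  list(Q = Q, lambda = lambda,
       W_rec = Q %*% (lambda * solve(Q)))
}

#' Simulate the linear eigenvector-subspace model
#'
#' Same task structure and input schedule as [simulate_bump_attractor()]
#' (target at full amplitude, distractor at 0.2, non-memory input of strength
#' `nonmemory_amplitude` during the distractor window), but with linear
#' dynamics in which each input is delivered along its own stable
#' (eigenvalue-1) eigenvector. Because the non-memory input is a single
#' direction shared by all conditions, it translates the population state
#' identically for every target location.
#'
#' @inheritParams simulate_bump_attractor
#' @param cfg A [linear_config()].
#' @return A [population_tensor()]; rates may be negative (the model is
#'   unbounded).
#' @export
simulate_linear_model <- function(cfg, timeline, n_trials_per_condition, seed) {
  if (missing(seed))
    stop("simulations must be seeded (reproducibility contract)", call. = FALSE)
  stopifnot(inherits(cfg, "linear_config"), inherits(timeline, "task_timeline"),
            n_trials_per_condition >= 1)
  spec <- condition_grid(cfg$n_locations, n_trials_per_condition)
  n <- cfg$n_units
  ta <- timeline$time_axis
  n_trials <- nrow(spec)

  with_local_seed(seed, {
    rec <- build_linear_recurrent(cfg)
    # Input loading: targets (and distractors, which reuse the target
    # channels) on stable eigenvectors 1..n_locations, non-memory on the next.
    E_loc <- rec$Q[, seq_len(cfg$n_locations), drop = FALSE]
    e_nm <- rec$Q[, cfg$n_locations + 1L]
    rates <- array(0, dim = c(n, length(ta), n_trials))
    R <- matrix(0, n, n_trials)
    in_window <- function(t, w) t >= w[1] && t < w[2]
    for (k in seq_along(ta)) {
      t <- ta[k]
      inp <- matrix(0, n, n_trials)
      if (in_window(t, timeline$target))
        inp <- inp + cfg$target_amplitude *
          E_loc[, spec$target_loc, drop = FALSE]
      if (in_window(t, timeline$distractor)) {
        inp <- inp + cfg$distractor_amplitude *
          E_loc[, spec$distractor_loc, drop = FALSE]
        inp <- inp + cfg$nonmemory_amplitude * e_nm
      }
      noise <- matrix(stats::rnorm(n * n_trials, sd = cfg$noise_sd), n, n_trials)
      R <- rec$W_rec %*% R + inp + noise
      rates[, k, ] <- R
    }
    tt <- data.frame(trial_id = seq_len(n_trials), session = 1L,
                     target_loc = spec$target_loc,
                     distractor_loc = spec$distractor_loc,
                     correct = TRUE)
    population_tensor(rates, ta, tt, bin_ms = timeline$step_ms,
                      meta = list(config = unclass(cfg), seed = seed,
                                  lambda = rec$lambda, model = "linear"))
  })
}
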
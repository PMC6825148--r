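#' Piecewise nonlinear activation function
#'
#' The saturating rate nonlinearity used by the bump-attractor network:
#' zero for negative drive, quadratic between 0 and 1, and a square-root
#' branch `sqrt(4x - 3)` above 1. The function is continuous everywhere
#' (both branches equal 1 at the knot).
#'
#' @param x Numeric vector of net input; must be finite.
#' @return Non-negative numeric vector of the same length.
#' @examples
#' activation_phi(c(-2, 0.5, 1, 3))
#' @export
activation_phi <- function(x) {
  if (!all(is.finite(x))) stop("non-finite input to activation_phi", call. = FALSE)
  y <- numeric(length(x))
  mid <- x > 0 & x <= 1
  hi <- x > 1
  y[mid] <- x[mid]^2
  y[hi] <- sqrt(4 * x[hi] - 3)
  dim(y) <- dim(x)
  y
}

#' Bump-attractor network configuration
#'
#' Parameters of the ring bump-attractor model: `n_locations` blocks of
#' `units_per_location` adjacent units on a ring, local excitation within
#' `excitation_radius` ring steps, uniform weak inhibition elsewhere, and a
#' fixed set of `nonmemory_units` random units that receive an input of
#' strength `nonmemory_amplitude` during distractor presentation regardless
#' of distractor position.
#'
#' Excitation/inhibition defaults were calibrated against two contracts: with
#' noise alone no unit may exceed 10% of the single-bump peak rate over a
#' full trial (no spontaneous bumps), and a target-evoked bump's block-mean
#' rate at the end of Delay 2 must retain at least half of its end-of-Delay-1
#' value (persistence). See [check_bump_calibration()].
#'
#' @param n_units Number of rate units (default 80).
#' @param n_locations Number of stimulus locations (default 8).
#' @param units_per_location Adjacent units driven per location input
#'   (default 10); `n_locations * units_per_location` must equal `n_units`.
#' @param excitation_weight,excitation_radius Local excitatory weight and its
#'   ring radius (entries with ring distance `<= excitation_radius` are
#'   excitatory, including the self weight).
#' @param inhibition_weight Magnitude of the uniform inhibition applied, with
#'   negative sign, outside the excitatory neighborhood (must be >= 0).
#' @param target_amplitude Input strength of the target stimulus (default 1).
#' @param distractor_amplitude Input strength of the distractor, as an
#'   absolute amplitude (default 0.2 of the target).
#' @param nonmemory_units Number `n` of non-memory units (default 10).
#' @param nonmemory_amplitude Non-memory input strength `s` (default 5).
#' @param noise_sd Standard deviation of the per-step Gaussian noise inside
#'   the activation argument (default 0.1).
#' @param input_jitter_sd Standard deviation (in ring units) of the seeded
#'   per-trial integer offset applied to the target and distractor input
#'   blocks. This emulates the trial-to-trial encoding variability (bump
#'   position diffusion) of continuous-attractor memory networks, which the
#'   discretized ring otherwise suppresses; 0 disables it.
#' @return An object of class `bump_config`.
#' @export
bump_config <- function(n_units = 80L,
                        n_locations = 8L,
                        units_per_location = 10L,
                        excitation_weight = 0.25,
                        excitation_radius = 2L,
                        inhibition_weight = 0.012,
                        target_amplitude = 1,
                        distractor_amplitude = 0.2 * target_amplitude,
                        nonmemory_units = 10L,
                        nonmemory_amplitude = 5,
                        noise_sd = 0.1,
                        input_jitter_sd = 2) {
  if (n_locations * units_per_location != n_units)
    stop("n_locations * units_per_location must equal n_units", call. = FALSE)
  if (nonmemory_units > n_units)
    stop("nonmemory_units cannot exceed n_units", call. = FALSE)
  if (inhibition_weight < 0)
    stop("inhibition_weight is a magnitude and must be >= 0", call. = FALSE)
  structure(list(n_units = as.integer(n_units),
                 n_locations = as.integer(n_locations),
                 units_per_location = as.integer(units_per_location),
                 excitation_weight = excitation_weight,
                 excitation_radius = as.integer(excitation_radius),
                 inhibition_weight = inhibition_weight,
                 target_amplitude = target_amplitude,
                 distractor_amplitude = distractor_amplitude,
                 nonmemory_units = as.integer(nonmemory_units),
                 nonmemory_amplitude = nonmemory_amplitude,
                 noise_sd = noise_sd,
                 input_jitter_sd = input_jitter_sd),
            class = "bump_config")
}

#' Recurrent weight matrix of the ring bump attractor
#'
#' Builds the symmetric circulant connectivity: `+excitation_weight` for unit
#' pairs within `excitation_radius` ring steps (including the diagonal) and
#' `-inhibition_weight` everywhere else.
#'
#' @param cfg A [bump_config()].
#' @return `n_units x n_units` numeric matrix.
#' @export
build_bump_weights <- function(cfg) {
  stopifnot(inherits(cfg, "bump_config"))
  n <- cfg$n_units
  if (cfg$excitation_radius >= n / 2)
    stop("excitation_radius must be below n_units/2 (excitation would be global)",
         call. = FALSE)
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  d <- pmin(d, n - d)
  W <- matrix(-cfg$inhibition_weight, n, n)
  W[d <= cfg$excitation_radius] <- cfg$excitation_weight
  W
}

# Units driven by location input `loc` (a contiguous block on the ring),
# optionally shifted by a per-trial integer offset (encoding jitter).
location_block <- function(cfg, loc, offset = 0L) {
  idx <- (loc - 1L) * cfg$units_per_location + seq_len(cfg$units_per_location)
  (idx - 1L + offset) %% cfg$n_units + 1L
}

# Core discrete-time engine shared by all bump scenarios. `trial_spec` has one
# row per trial with columns target_loc, distractor_loc, correct, and optional
# distractor2_loc, target_gain, extra_noise_sd. `nonmemory_at` names the
# distractor windows in which the fixed non-memory unit set receives input.
simulate_ring_core <- function(cfg, timeline, trial_spec, seed,
                               nonmemory_at = "distractor",
                               linear = FALSE, W = NULL, W_in = NULL) {
  n_trials <- nrow(trial_spec)
  if (is.null(trial_spec$target_gain)) trial_spec$target_gain <- 1
  if (is.null(trial_spec$extra_noise_sd)) trial_spec$extra_noise_sd <- 0
  if (is.null(trial_spec$correct)) trial_spec$correct <- TRUE
  ta <- timeline$time_axis
  n_steps <- length(ta)
  n <- cfg$n_units
  if (is.null(W)) W <- build_bump_weights(cfg)

  with_local_seed(seed, {
    nm_units <- sort(sample.int(n, cfg$nonmemory_units))
    rates <- array(0, dim = c(n, n_steps, n_trials))
    R <- matrix(0, n, n_trials)
    noise_sd <- cfg$noise_sd + trial_spec$extra_noise_sd
    jit <- cfg$input_jitter_sd %||% 0
    draw_offsets <- function() {
      if (jit > 0) as.integer(round(stats::rnorm(n_trials, sd = jit)))
      else integer(n_trials)
    }
    off_target <- draw_offsets()

    in_window <- function(t, w) t >= w[1] && t < w[2]
    dist_windows <- grep("^distractor", names(timeline), value = TRUE)
    off_dist <- stats::setNames(
      replicate(length(dist_windows), draw_offsets(), simplify = FALSE),
      dist_windows)
    for (k in seq_len(n_steps)) {
      t <- ta[k]
      inp <- matrix(0, n, n_trials)
      if (in_window(t, timeline$target)) {
        for (tr in seq_len(n_trials)) {
          blk <- location_block(cfg, trial_spec$target_loc[tr], off_target[tr])
          inp[blk, tr] <- inp[blk, tr] +
            cfg$target_amplitude * trial_spec$target_gain[tr]
        }
      }
      for (dw in dist_windows) {
        if (!in_window(t, timeline[[dw]])) next
        loc_col <- if (dw == "distractor") "distractor_loc" else paste0(dw, "_loc")
        for (tr in seq_len(n_trials)) {
          blk <- location_block(cfg, trial_spec[[loc_col]][tr],
                                off_dist[[dw]][tr])
          inp[blk, tr] <- inp[blk, tr] + cfg$distractor_amplitude
        }
        if (dw %in% nonmemory_at)
          inp[nm_units, ] <- inp[nm_units, ] + cfg$nonmemory_amplitude
      }
      noise <- matrix(stats::rnorm(n * n_trials), n, n_trials) *
        rep(noise_sd, each = n)
      X <- W %*% R + (if (is.null(W_in)) inp else W_in %*% inp) + noise
      R <- if (linear) X else activation_phi(X)
      rates[, k, ] <- R
    }

    tt <- data.frame(trial_id = seq_len(n_trials),
                     session = 1L,
                     target_loc = trial_spec$target_loc,
                     distractor_loc = trial_spec$distractor_loc,
                     correct = trial_spec$correct)
    extra_cols <- setdiff(names(trial_spec),
                          c(names(tt), "target_gain", "extra_noise_sd"))
    for (cc in extra_cols) tt[[cc]] <- trial_spec[[cc]]
    population_tensor(rates, ta, tt, bin_ms = timeline$step_ms,
                      meta = list(config = unclass(cfg), seed = seed,
                                  nonmemory_ids = nm_units,
                                  nonmemory_at = nonmemory_at,
                                  model = if (linear) "linear" else "bump"))
  })
}

# Balanced (target, distractor) condition grid, distractor != target.
condition_grid <- function(n_locations, n_trials_per_condition) {
  g <- expand.grid(target_loc = seq_len(n_locations),
                   distractor_loc = seq_len(n_locations))
  g <- g[g$target_loc != g$distractor_loc, , drop = FALSE]
  g[rep(seq_len(nrow(g)), each = n_trials_per_condition), , drop = FALSE]
}

#' Simulate the bump-attractor model of the distractor task
#'
#' Runs the discrete-time rate dynamics `r[t+1] = phi(W r[t] + W_in I[t] +
#' noise)` for every (target, distractor) condition. The target input drives
#' its 10-unit block during the target window; the distractor input (at 0.2
#' of the target amplitude by default) drives the distractor block during the
#' distractor window; and a fixed, seeded random set of non-memory units
#' receives input of strength `nonmemory_amplitude` during the distractor
#' window, regardless of distractor position. The initial state is zero and
#' the baseline window is simulated with noise only.
#'
#' @param cfg A [bump_config()].
#' @param timeline A [task_timeline()].
#' @param n_trials_per_condition Trials per (target, distractor) pair.
#' @param seed Integer seed (required; output is bit-reproducible given the
#'   seed).
#' @return A [population_tensor()] with `bin_ms` equal to the simulation step.
#' @export
simulate_bump_attractor <- function(cfg, timeline, n_trials_per_condition,
                                    seed) {
  if (missing(seed))
    stop("simulations must be seeded (reproducibility contract)", call. = FALSE)
  stopifnot(inherits(cfg, "bump_config"), inherits(timeline, "task_timeline"),
            n_trials_per_condition >= 1)
  spec <- condition_grid(cfg$n_locations, n_trials_per_condition)
  simulate_ring_core(cfg, timeline, spec, seed)
}

#' Check the bump-attractor calibration contracts
#'
#' Verifies, by direct simulation, the two contracts the default weights were
#' calibrated against: (i) no spontaneous bumps — with default noise and no
#' inputs, no unit's rate exceeds 10% of the single-bump peak over a full
#' trial; (ii) persistence — after a target pulse (no distractor, no
#' non-memory input), the target block's mean rate at the end of Delay 2 is
#' at least half its end-of-Delay-1 value.
#'
#' @param cfg A [bump_config()].
#' @param timeline A [task_timeline()].
#' @param seed Integer seed.
#' @param n_trials Trials used for each probe simulation.
#' @return List with logical `no_spontaneous_bumps`, `bump_persists`, and the
#'   measured quantities.
#' @export
check_bump_calibration <- function(cfg, timeline = task_timeline(), seed = 1L,
                                   n_trials = 10L) {
  quiet_cfg <- cfg
  quiet_cfg$target_amplitude <- 0
  quiet_cfg$distractor_amplitude <- 0
  quiet_cfg$nonmemory_amplitude <- 0
  spec <- data.frame(target_loc = 1L, distractor_loc = 2L)[rep(1, n_trials), ]
  quiet <- simulate_ring_core(quiet_cfg, timeline, spec, seed)

  pulse_cfg <- cfg
  pulse_cfg$distractor_amplitude <- 0
  pulse_cfg$nonmemory_amplitude <- 0
  pulse <- simulate_ring_core(pulse_cfg, timeline, spec, seed)

  blk <- location_block(cfg, 1L)
  ta <- timeline$time_axis
  end_d1 <- which.min(abs(ta - (timeline$delay1[2] - timeline$step_ms)))
  end_d2 <- which.min(abs(ta - (timeline$delay2[2] - timeline$step_ms)))
  peak <- max(pulse$rates[blk, , ])
  r_d1 <- mean(pulse$rates[blk, end_d1, ])
  r_d2 <- mean(pulse$rates[blk, end_d2, ])
  list(no_spontaneous_bumps = max(quiet$rates) < 0.1 * peak,
       bump_persists = r_d1 >= 0.25 * peak && r_d2 >= 0.5 * r_d1,
       peak_rate = peak, max_quiet_rate = max(quiet$rates),
       end_delay1_rate = r_d1, end_delay2_rate = r_d2)
}
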
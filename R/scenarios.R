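#' Simulate task-variant scenarios of the bump-attractor model
#'
#' Variants of the basic distractor task used for model predictions and
#' error-trial analyses:
#'
#' * `error_trials`: a fraction of trials is simulated with a degraded target
#'   encoding — the target input amplitude is multiplied by
#'   `params$degradation` and optional extra per-step noise
#'   (`params$extra_noise_sd`) is added — and flagged `correct = FALSE`.
#'   The degradation mechanism is an assumption of this package (error
#'   aetiology is not observable in the generative model).
#' * `two_distractors_stimulus_triggered`: extended timeline with a second
#'   distractor and third delay; the non-memory input fires at *every*
#'   distractor.
#' * `two_distractors_proximity_triggered`: same timeline; the non-memory
#'   input fires only at the *final* distractor.
#' * `distractor_level_sweep`: grid over distractor amplitudes, returning a
#'   table of full-space cross-delay decoding summaries.
#' * `nonmemory_ns_sweep`: grid over (n, s) non-memory parameter pairs,
#'   returning the same summary table.
#'
#' @param base_cfg A [bump_config()].
#' @param scenario One of `"error_trials"`,
#'   `"two_distractors_stimulus_triggered"`,
#'   `"two_distractors_proximity_triggered"`, `"distractor_level_sweep"`,
#'   `"nonmemory_ns_sweep"`.
#' @param params Named list of scenario parameters (see Details above);
#'   sweeps take `values` (a vector of amplitudes, or a 2-column matrix /
#'   data frame of `n`, `s` pairs) plus `n_trials_per_condition` and
#'   decoding settings `n_responses`, `n_resamples`.
#' @param seed Integer seed.
#' @param timeline A [task_timeline()]; for two-distractor scenarios the
#'   extended timeline is built internally.
#' @param n_trials_per_condition Trials per condition for non-sweep scenarios.
#' @return A [population_tensor()] for the first three scenarios; a data
#'   frame of `(value, lp11, lp12, lp11_minus_lp12)` rows for the sweeps.
#' @export
simulate_scenario <- function(base_cfg, scenario, params = list(), seed,
                              timeline = task_timeline(),
                              n_trials_per_condition = 10L) {
  stopifnot(inherits(base_cfg, "bump_config"))
  scenario <- match.arg(scenario,
                        c("error_trials",
                          "two_distractors_stimulus_triggered",
                          "two_distractors_proximity_triggered",
                          "distractor_level_sweep",
                          "nonmemory_ns_sweep"))
  switch(scenario,
    error_trials = scenario_error_trials(base_cfg, params, seed, timeline,
                                         n_trials_per_condition),
    two_distractors_stimulus_triggered =
      scenario_two_distractors(base_cfg, params, seed, n_trials_per_condition,
                               nonmemory_at = c("distractor", "distractor2")),
    two_distractors_proximity_triggered =
      scenario_two_distractors(base_cfg, params, seed, n_trials_per_condition,
                               nonmemory_at = "distractor2"),
    distractor_level_sweep =
      scenario_sweep(base_cfg, params, seed, timeline, which = "distractor"),
    nonmemory_ns_sweep =
      scenario_sweep(base_cfg, params, seed, timeline, which = "nonmemory"))
}

scenario_error_trials <- function(cfg, params, seed, timeline,
                                  n_trials_per_condition) {
  frac <- params$error_fraction %||% 0.25
  degr <- params$degradation %||% 0.5
  extra <- params$extra_noise_sd %||% 0
  if (frac < 0 || frac > 1) stop("error_fraction must be in [0, 1]", call. = FALSE)
  spec <- condition_grid(cfg$n_locations, n_trials_per_condition)
  n_tr <- nrow(spec)
  err <- with_local_seed(stage_seed(seed, 99L),
                         sample(c(TRUE, FALSE), n_tr, replace = TRUE,
                                prob = c(frac, 1 - frac)))
  spec$correct <- !err
  spec$target_gain <- ifelse(err, degr, 1)
  spec$extra_noise_sd <- ifelse(err, extra, 0)
  simulate_ring_core(cfg, timeline, spec, seed)
}

scenario_two_distractors <- function(cfg, params, seed, n_trials_per_condition,
                                     nonmemory_at) {
  tl <- task_timeline(extra = list(distractor2 = c(2600, 2900),
                                   delay3 = c(2900, 3900)))
  spec <- condition_grid(cfg$n_locations, n_trials_per_condition)
  # second distractor drawn independently, also != target
  spec$distractor2_loc <- with_local_seed(stage_seed(seed, 98L), {
    vapply(spec$target_loc, function(t)
      sample(setdiff(seq_len(cfg$n_locations), t), 1L), integer(1))
  })
  simulate_ring_core(cfg, tl, spec, seed, nonmemory_at = nonmemory_at)
}

# Shared sweep driver: simulate at each grid point and summarize full-space
# cross-delay decoding (lp11 vs lp12) at reduced problem size.
scenario_sweep <- function(cfg, params, seed, timeline, which) {
  values <- params$values
  if (is.null(values))
    stop("sweep scenarios need params$values", call. = FALSE)
  ntr <- params$n_trials_per_condition %||% 5L
  n_resp <- params$n_responses %||% 20L
  n_res <- params$n_resamples %||% 50L
  if (which == "nonmemory") {
    values <- as.data.frame(values)
    if (ncol(values) != 2L)
      stop("nonmemory_ns_sweep needs 2-column values (n, s)", call. = FALSE)
    names(values) <- c("n", "s")
  }
  rows <- lapply(seq_len(NROW(values)), function(i) {
    cfg_i <- cfg
    if (which == "distractor") {
      cfg_i$distractor_amplitude <- values[i]
    } else {
      cfg_i$nonmemory_units <- as.integer(values$n[i])
      cfg_i$nonmemory_amplitude <- values$s[i]
    }
    x <- simulate_bump_attractor(cfg_i, timeline, ntr, seed = stage_seed(seed, i))
    lp <- quick_lp_summary(x, n_responses = n_resp, n_resamples = n_res,
                           seed = stage_seed(seed, 1000L + i))
    if (which == "distractor")
      data.frame(distractor_amplitude = values[i], lp)
    else
      data.frame(n = values$n[i], s = values$s[i], lp)
  })
  do.call(rbind, rows)
}

# Minimal full-space LP summary used by the parameter sweeps.
quick_lp_summary <- function(x, n_responses, n_resamples, seed,
                             locations = NULL) {
  if (is.null(locations))
    locations <- seq_len(min(7L, max(x$trial_table$target_loc)))
  binned <- bin_rates(x, bin_ms = 100, step_ms = 50)
  z <- zscore_baseline(binned, baseline = c(-300, 0))
  pp <- build_pseudopopulation(list(z), n_responses_per_location = n_responses,
                               locations = locations,
                               seed = stage_seed(seed, 1L))
  fs <- fit_full_space(pp, window = c(800, 2500), variance_threshold = 0.9)
  proj <- project_full_space(pp, fs)
  ct <- cross_temporal_decode(proj,
                              train_window = list(c(800, 1300), c(1800, 2300)),
                              n_resamples = n_resamples,
                              seed = stage_seed(seed, 2L))
  lp <- lp_statistics(ct, d1_window = c(800, 1300), d2_window = c(1800, 2300))
  data.frame(lp11 = mean(lp$lp11), lp12 = mean(lp$lp12),
             lp11_minus_lp12 = mean(lp$diff_11_12))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
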
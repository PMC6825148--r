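#' Configuration for a full analysis run
#'
#' Bundles the generator, preprocessing, subspace, decoding, and state-space
#' parameters of [run_pipeline()] into one serializable list. Per-stage seeds
#' are derived deterministically from the master `seed` (see
#' `morphspace:::stage_seed`), so any stage can be re-run in isolation.
#'
#' @param model `"bump"` or `"linear"`.
#' @param model_cfg A [bump_config()] or [linear_config()]; defaults to the
#'   calibrated default configuration of the chosen model.
#' @param timeline A [task_timeline()].
#' @param n_trials_per_condition Simulated trials per (target, distractor)
#'   pair (default 20).
#' @param n_responses Pseudo-trials per location (default 50).
#' @param locations Analyzed target locations (default `1:7`).
#' @param bin_ms,step_ms Analysis binning (default 100/50 ms).
#' @param baseline_window,pca_window,d1_window,d2_window,distractor_window
#'   Analysis windows in ms.
#' @param variance_threshold PCA variance fraction for the full space
#'   (default 0.9).
#' @param beta,u_dim,n_starts,constraint Subspace optimization settings; the
#'   pipeline defaults to the `"orthonormal"` mode (see
#'   [optimize_subspace()]), and `u_dim` is additionally capped at half the
#'   fitted full-space dimensionality.
#' @param n_resamples,train_frac Decoding resampling settings.
#' @param n_boot Bootstrap count for state-space statistics.
#' @param include_shuffle Run the shuffled-label control (default `TRUE`).
#' @param include_nonmemory_control Re-run the decoding with the non-memory
#'   input silenced (default `FALSE`).
#' @param include_error_trials Run the error-trial analysis (default
#'   `FALSE`).
#' @param error_params Parameters for the error-trial scenario (see
#'   [simulate_scenario()]).
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(model = c("bump", "linear"),
                            model_cfg = NULL,
                            timeline = task_timeline(),
                            n_trials_per_condition = 20L,
                            n_responses = 50L,
                            locations = 1:7,
                            bin_ms = 100, step_ms = 50,
                            baseline_window = c(-300, 0),
                            pca_window = c(800, 2500),
                            d1_window = c(800, 1300),
                            d2_window = c(1800, 2300),
                            distractor_window = c(1300, 1600),
                            variance_threshold = 0.9,
                            beta = 0.1, u_dim = 8L, n_starts = 5L,
                            constraint = "orthonormal",
                            n_resamples = 200L, train_frac = 0.8,
                            n_boot = 200L,
                            include_shuffle = TRUE,
                            include_nonmemory_control = FALSE,
                            include_error_trials = FALSE,
                            error_params = list(),
                            seed = 1L) {
  model <- match.arg(model)
  if (is.null(model_cfg))
    model_cfg <- if (model == "bump") bump_config() else linear_config()
  cfg <- list(model = model, model_cfg = model_cfg, timeline = timeline,
              n_trials_per_condition = as.integer(n_trials_per_condition),
              n_responses = as.integer(n_responses), locations = locations,
              bin_ms = bin_ms, step_ms = step_ms,
              baseline_window = baseline_window, pca_window = pca_window,
              d1_window = d1_window, d2_window = d2_window,
              distractor_window = distractor_window,
              variance_threshold = variance_threshold,
              beta = beta, u_dim = as.integer(u_dim),
              n_starts = as.integer(n_starts), constraint = constraint,
              n_resamples = as.integer(n_resamples), train_frac = train_frac,
              n_boot = as.integer(n_boot),
              include_shuffle = include_shuffle,
              include_nonmemory_control = include_nonmemory_control,
              include_error_trials = include_error_trials,
              error_params = error_params,
              seed = as.integer(seed))
  cfg$hash <- fnv1a_hash(paste(utils::capture.output(utils::str(cfg)),
                               collapse = "\n"))
  structure(cfg, class = "run_config")
}

# simulate + bin + zscore + pseudopopulation + full space + projection,
# shared by the main run and its controls.
prepare_projection <- function(config, model_cfg, seed) {
  x <- if (config$model == "bump")
    simulate_bump_attractor(model_cfg, config$timeline,
                            config$n_trials_per_condition, seed = seed)
  else
    simulate_linear_model(model_cfg, config$timeline,
                          config$n_trials_per_condition, seed = seed)
  binned <- bin_rates(x, bin_ms = config$bin_ms, step_ms = config$step_ms)
  z <- zscore_baseline(binned, baseline = config$baseline_window)
  pp <- build_pseudopopulation(list(z),
                               n_responses_per_location = config$n_responses,
                               locations = config$locations,
                               seed = stage_seed(seed, 2L))
  fs <- fit_full_space(pp, window = config$pca_window,
                       variance_threshold = config$variance_threshold)
  list(raw = x, z = z, pp = pp, fullspace = fs,
       proj = project_full_space(pp, fs))
}

# decode + LP statistics in one space
lp_in_space <- function(proj, config, seed, space_tag = proj$space) {
  ct <- cross_temporal_decode(
    proj, train_window = list(config$d1_window, config$d2_window),
    n_resamples = config$n_resamples, train_frac = config$train_frac,
    seed = seed, space_tag = space_tag)
  lp_statistics(ct, config$d1_window, config$d2_window)
}

#' Run the full morphing-subspace analysis
#'
#' Orchestrates simulation, preprocessing, subspace optimization, decoding,
#' and state-space statistics into one reproducible report: full-space and
#' subspace LP statistics, normalized cluster-shift distributions in both
#' spaces, the trajectory-parallelism (PLV) comparison between the true and
#' label-shuffled subspaces, the subspace variance curve and neuron
#' contribution weights, and the selectivity classification of the simulated
#' units — plus the shuffled-label, non-memory-silenced, and error-trial
#' analyses when enabled in the configuration.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `report_bundle` (a named list; see the fields
#'   in the examples and the package vignette).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  prep <- prepare_projection(config, config$model_cfg, stage_seed(seed, 1L))
  proj <- prep$proj
  dm <- build_delay_matrices(proj, d1_window = config$d1_window,
                             d2_window = config$d2_window)
  # the subspace must be a proper subspace of the fitted full space and must
  # leave room for the morph directions it is meant to exclude; when the
  # data's 90%-variance dimensionality is small, cap u_dim at half of it
  u_dim <- min(config$u_dim, max(2L, prep$fullspace$n_components %/% 2L))
  if (u_dim < config$u_dim)
    message("u_dim clamped to ", u_dim, " (full space has ",
            prep$fullspace$n_components, " components)")
  map <- optimize_subspace(dm, beta = config$beta, u_dim = u_dim,
                           seed = stage_seed(seed, 3L),
                           n_starts = config$n_starts,
                           constraint = config$constraint)
  proj_sub <- project_tensor(proj, map, "subspace")

  lp_full <- lp_in_space(proj, config, stage_seed(seed, 4L), "full")
  lp_sub <- lp_in_space(proj_sub, config, stage_seed(seed, 5L), "subspace")

  shift_full <- cluster_shift_stats(proj, config$d1_window, config$d2_window,
                                    config$distractor_window,
                                    delay1_period = config$timeline$delay1,
                                    delay2_period = config$timeline$delay2,
                                    n_boot = config$n_boot,
                                    seed = stage_seed(seed, 6L))
  shift_sub <- cluster_shift_stats(proj_sub, config$d1_window, config$d2_window,
                                   config$distractor_window,
                                   delay1_period = config$timeline$delay1,
                                   delay2_period = config$timeline$delay2,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(seed, 6L))

  selectivity <- classify_selectivity(
    list(z = prep$z$z, time_axis = prep$z$time_axis, bin_ms = prep$z$bin_ms,
         labels = prep$z$trial_table$target_loc),
    d1_window = config$d1_window, d2_window = config$d2_window)

  report <- list(
    config = config,
    fullspace = prep$fullspace,
    map = map,
    lp = list(full = lp_full, subspace = lp_sub),
    shifts = list(full = shift_full, subspace = shift_sub),
    variance_curve = subspace_variance_curve(map, dm),
    contributions = neuron_contributions(map, prep$fullspace),
    selectivity = selectivity,
    selectivity_fractions = selectivity_fractions(selectivity))

  if (config$include_shuffle) {
    proj_shuf <- shuffle_delay2_trials(proj,
                                       from_ms = config$distractor_window[1],
                                       seed = stage_seed(seed, 7L))
    dm_shuf <- build_delay_matrices(proj_shuf, d1_window = config$d1_window,
                                    d2_window = config$d2_window)
    map_shuf <- optimize_subspace(dm_shuf, beta = config$beta,
                                  u_dim = map$u_dim,
                                  seed = stage_seed(seed, 8L),
                                  n_starts = config$n_starts,
                                  constraint = config$constraint)
    proj_shuf_sub <- project_tensor(proj_shuf, map_shuf, "subspace")
    # trajectory parallelism is a property of the data's D1->D2 displacements,
    # measured in the full space (the optimized subspace deliberately removes
    # those displacements); subspace-projected PLVs are retained as well
    report$shuffle <- list(
      map = map_shuf,
      lp_subspace = lp_in_space(proj_shuf_sub, config, stage_seed(seed, 9L),
                                "subspace"),
      plv_true = plv_bootstrap(proj, config$d1_window, config$d2_window,
                               n_boot = config$n_boot,
                               seed = stage_seed(seed, 10L)),
      plv_shuffled = plv_bootstrap(proj_shuf, config$d1_window,
                                   config$d2_window, n_boot = config$n_boot,
                                   seed = stage_seed(seed, 10L)),
      plv_true_subspace = plv_bootstrap(proj_sub, config$d1_window,
                                        config$d2_window,
                                        n_boot = config$n_boot,
                                        seed = stage_seed(seed, 10L)),
      plv_shuffled_subspace = plv_bootstrap(proj_shuf_sub, config$d1_window,
                                            config$d2_window,
                                            n_boot = config$n_boot,
                                            seed = stage_seed(seed, 10L)))
  }

  if (config$include_nonmemory_control && config$model == "bump") {
    cfg0 <- config$model_cfg
    cfg0$nonmemory_amplitude <- 0
    prep0 <- prepare_projection(config, cfg0, stage_seed(seed, 11L))
    report$nonmemory_control <- list(
      lp_full = lp_in_space(prep0$proj, config, stage_seed(seed, 12L), "full"))
  }

  if (config$include_error_trials && config$model == "bump") {
    report$error_trials <- run_error_analysis(config, map, prep,
                                              stage_seed(seed, 13L))
  }
  class(report) <- "report_bundle"
  report
}

# Error-trial arm: simulate a mixed correct/error dataset, keep the locations
# with enough errors, build correct and error pseudo-populations in the
# *main run's* full space, and compare decoding across spaces.
run_error_analysis <- function(config, map, prep, seed) {
  params <- utils::modifyList(list(error_fraction = 0.3, degradation = 0.5,
                                   min_errors_per_session = 6L,
                                   max_locations = 4L),
                              config$error_params)
  x <- simulate_scenario(config$model_cfg, "error_trials", params, seed,
                         timeline = config$timeline,
                         n_trials_per_condition = config$n_trials_per_condition)
  locs <- filter_error_locations(x$trial_table,
                                 params$min_errors_per_session)
  locs <- intersect(locs, config$locations)
  if (length(locs) < 2L)
    return(list(status = "no analyzable error locations", locations = locs))
  locs <- locs[seq_len(min(length(locs), params$max_locations))]
  binned <- bin_rates(x, bin_ms = config$bin_ms, step_ms = config$step_ms)
  z <- zscore_baseline(binned, baseline = config$baseline_window)
  pp_c <- build_pseudopopulation(list(z),
                                 n_responses_per_location = config$n_responses,
                                 locations = locs, seed = stage_seed(seed, 1L),
                                 correct_only = TRUE)
  z_err <- z
  z_err$trial_table <- z$trial_table
  z_err$trial_table$correct <- !z$trial_table$correct   # select error trials
  pp_e <- build_pseudopopulation(list(z_err),
                                 n_responses_per_location = config$n_responses,
                                 locations = locs, seed = stage_seed(seed, 2L),
                                 correct_only = TRUE)
  proj_c <- project_full_space(pp_c, prep$fullspace)
  proj_e <- project_full_space(pp_e, prep$fullspace)
  perf <- error_trial_performance(proj_c, proj_e, map,
                                  d1_window = config$d1_window,
                                  d2_window = config$d2_window,
                                  n_resamples = config$n_resamples,
                                  train_frac = config$train_frac,
                                  seed = stage_seed(seed, 3L))
  c(perf, list(status = "ok", locations = locs))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("morphspace report (config hash ", x$config$hash, ")\n", sep = "")
  cat(sprintf("  full space: %d components\n", x$fullspace$n_components))
  s <- function(v) sprintf("%.3f [%.3f, %.3f]", mean(v),
                           stats::quantile(v, 0.025), stats::quantile(v, 0.975))
  cat("  LP11 - LP12: full ", s(x$lp$full$diff_11_12),
      " | subspace ", s(x$lp$subspace$diff_11_12), "\n", sep = "")
  cat("  LP22 - LP21: full ", s(x$lp$full$diff_22_21),
      " | subspace ", s(x$lp$subspace$diff_22_21), "\n", sep = "")
  cat("  normalized inter-delay shift: full ",
      s(x$shifts$full$normalized_inter_delay), " | subspace ",
      s(x$shifts$subspace$normalized_inter_delay), "\n", sep = "")
  cat("  selectivity fractions: ",
      paste(names(x$selectivity_fractions),
            sprintf("%.2f", x$selectivity_fractions), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$shuffle))
    cat("  PLV true ", s(x$shuffle$plv_true$plv), " | shuffled ",
        s(x$shuffle$plv_shuffled$plv), "\n", sep = "")
  invisible(x)
}

#' Write a report bundle to JSON
#'
#' Serializes the numeric tables of a [run_pipeline()] report (means and 95%
#' intervals of every distribution, selectivity fractions, variance curve,
#' convergence metadata, config hash and seed) to a machine-readable JSON
#' file.
#'
#' @param report A `report_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  summ <- function(v) list(mean = mean(v),
                           ci = as.numeric(stats::quantile(v, c(0.025, 0.975))))
  out <- list(
    config_hash = report$config$hash,
    seed = report$config$seed,
    model = report$config$model,
    n_components = report$fullspace$n_components,
    converged = report$map$converged,
    lp = lapply(report$lp, function(l)
      lapply(l[c("lp11", "lp12", "lp22", "lp21", "diff_11_12", "diff_22_21")],
             summ)),
    shifts = lapply(report$shifts, function(s)
      lapply(s[c("normalized_inter_delay", "normalized_intra_delay",
                 "normalized_d1_to_distractor")], summ)),
    selectivity_fractions = as.list(report$selectivity_fractions),
    variance_curve = report$variance_curve)
  if (!is.null(report$shuffle))
    out$shuffle <- list(plv_true = summ(report$shuffle$plv_true$plv),
                        plv_shuffled = summ(report$shuffle$plv_shuffled$plv),
                        lp_diff_11_12 = summ(report$shuffle$lp_subspace$diff_11_12))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
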
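#' Re-bin a population tensor with overlapping windows
#'
#' Averages rates in sliding windows of `bin_ms`, advancing by `step_ms`
#' (default: 100 ms windows with 50 ms steps). Each output bin is the mean
#' over the half-open interval `[t, t + bin_ms)`; the number of output bins
#' is `floor((T - bin_ms) / step_ms) + 1` for a recording of length `T`.
#'
#' @param x A [population_tensor()].
#' @param bin_ms Output bin width in ms (must be >= `step_ms` and fit inside
#'   the recording).
#' @param step_ms Bin advance in ms.
#' @return A [population_tensor()] on the new time axis.
#' @export
bin_rates <- function(x, bin_ms = 100, step_ms = 50) {
  stopifnot(inherits(x, "population_tensor"))
  if (bin_ms < step_ms) stop("bin_ms must be >= step_ms", call. = FALSE)
  t0 <- x$time_axis[1]
  t_end <- x$time_axis[length(x$time_axis)] + x$bin_ms
  if (bin_ms > t_end - t0) stop("bin wider than the recording", call. = FALSE)
  starts <- seq(t0, t_end - bin_ms, by = step_ms)
  d <- dim(x$rates)
  out <- array(0, dim = c(d[1], length(starts), d[3]))
  for (j in seq_along(starts)) {
    idx <- which(x$time_axis >= starts[j] & x$time_axis < starts[j] + bin_ms)
    out[, j, ] <- if (length(idx) == 1L) x$rates[, idx, ]
      else apply(x$rates[, idx, , drop = FALSE], c(1, 3), mean)
  }
  population_tensor(out, starts, x$trial_table, bin_ms = bin_ms, meta = x$meta)
}

#' Baseline z-scoring of binned rates
#'
#' Normalizes each neuron by the mean and standard deviation of its rates in
#' the pre-target baseline window, pooled over all baseline bins and trials.
#' A floor (`sd_floor`, default 1e-6 rate units) is applied to the standard
#' deviation, so silent neurons map to all-zero z-scores and are flagged
#' rather than dropped.
#'
#' @param x A binned [population_tensor()].
#' @param baseline `[start, end)` window in ms used for the statistics.
#' @param sd_floor Minimum standard deviation.
#' @return An object of class `zscored_tensor`: the tensor plus
#'   `baseline_stats` (per-neuron mean/sd and a `floored` flag).
#' @export
zscore_baseline <- function(x, baseline = c(-300, 0), sd_floor = 1e-6) {
  stopifnot(inherits(x, "population_tensor"))
  idx <- bins_in_window(x$time_axis, x$bin_ms, baseline)
  base <- x$rates[, idx, , drop = FALSE]
  n <- dim(x$rates)[1]
  mu <- numeric(n); sdv <- numeric(n)
  for (i in seq_len(n)) {
    v <- base[i, , ]
    mu[i] <- mean(v)
    sdv[i] <- stats::sd(as.vector(v))
  }
  floored <- sdv < sd_floor
  sd_use <- pmax(sdv, sd_floor)
  z <- sweep(sweep(x$rates, 1, mu, "-"), 1, sd_use, "/")
  structure(list(z = z, time_axis = x$time_axis, bin_ms = x$bin_ms,
                 trial_table = x$trial_table,
                 baseline_stats = data.frame(neuron = seq_len(n), mean = mu,
                                             sd = sdv, floored = floored),
                 meta = x$meta),
            class = "zscored_tensor")
}

#' @export
print.zscored_tensor <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("zscored_tensor: %d neurons x %d bins x %d trials (%d sd-floored)\n",
              d[1], d[2], d[3], sum(x$baseline_stats$floored)))
  invisible(x)
}

#' Assemble a pseudo-population of condition-matched responses
#'
#' Builds pseudo-trials by sampling, for each analyzed target location and
#' each of `n_responses_per_location` responses, one correct trial *per
#' neuron independently* (with replacement only when a session has fewer
#' trials than requested), then concatenating neurons across sessions. This
#' deliberately discards cross-neuron noise correlations, as in standard
#' pseudo-population decoding.
#'
#' @param sessions List of `zscored_tensor` objects, one per recording
#'   session.
#' @param n_responses_per_location Pseudo-trials drawn per location
#'   (default 50).
#' @param locations Target locations to analyze (default `1:7`); a location
#'   missing from any session is excluded with a warning.
#' @param seed Integer seed; the per-neuron trial assignment is recorded in
#'   `attr(, "audit")` and is reproducible.
#' @param correct_only Use only correct trials (default `TRUE`).
#' @return A `pseudo_population`: list with `z` (neurons x bins x
#'   pseudo-trials), `labels` (location per pseudo-trial), `time_axis`,
#'   `bin_ms`.
#' @export
build_pseudopopulation <- function(sessions, n_responses_per_location = 50L,
                                   locations = 1:7, seed,
                                   correct_only = TRUE) {
  stopifnot(is.list(sessions), length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "zscored_tensor")))
  keep <- locations
  for (s in sessions) {
    tt <- s$trial_table
    if (correct_only) tt <- tt[tt$correct, , drop = FALSE]
    have <- unique(tt$target_loc)
    miss <- setdiff(keep, have)
    if (length(miss)) {
      warning("locations ", paste(miss, collapse = ", "),
              " missing from a session; excluded")
      keep <- setdiff(keep, miss)
    }
  }
  if (length(keep) < 2L) stop("fewer than 2 analyzable locations", call. = FALSE)
  n_bins <- dim(sessions[[1]]$z)[2]
  n_resp <- n_responses_per_location
  n_neurons <- sum(vapply(sessions, function(s) dim(s$z)[1], integer(1)))
  n_pseudo <- length(keep) * n_resp
  z <- array(0, dim = c(n_neurons, n_bins, n_pseudo))
  labels <- rep(keep, each = n_resp)
  audit <- vector("list", length(sessions))

  with_local_seed(seed, {
    row0 <- 0L
    for (si in seq_along(sessions)) {
      s <- sessions[[si]]
      tt <- s$trial_table
      ok <- if (correct_only) which(tt$correct) else seq_len(nrow(tt))
      nn <- dim(s$z)[1]
      idx_rec <- array(NA_integer_, dim = c(nn, length(keep), n_resp))
      for (li in seq_along(keep)) {
        pool <- ok[tt$target_loc[ok] == keep[li]]
        replace <- n_resp > length(pool)
        for (ni in seq_len(nn)) {
          pick <- sample(pool, n_resp, replace = replace)
          idx_rec[ni, li, ] <- pick
          cols <- (li - 1L) * n_resp + seq_len(n_resp)
          z[row0 + ni, , cols] <- s$z[ni, , pick]
        }
      }
      audit[[si]] <- idx_rec
      row0 <- row0 + nn
    }
  })
  structure(list(z = z, labels = labels, time_axis = sessions[[1]]$time_axis,
                 bin_ms = sessions[[1]]$bin_ms,
                 n_responses = n_resp, locations = keep,
                 audit = audit),
            class = "pseudo_population")
}

#' Fit the PCA full space
#'
#' Principal components of the z-scored pseudo-population activity, fit on
#' all (pseudo-trial, bin) samples within the given window, keeping the
#' smallest number of components whose cumulative explained variance reaches
#' `variance_threshold` (default 90%).
#'
#' @param pp A `pseudo_population` (or `zscored_tensor`).
#' @param window `[start, end)` fit window in ms (default 800-2500 ms after
#'   target onset: 500 ms before the end of Delay 1 through the end of the
#'   trial analysis epoch).
#' @param variance_threshold Fraction in (0, 1].
#' @return An object of class `full_space`: `loadings` (components x
#'   neurons, orthonormal rows), `center`, `explained_variance_fractions`,
#'   `n_components`, `fit_window`.
#' @export
fit_full_space <- function(pp, window = c(800, 2500), variance_threshold = 0.9) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  z <- if (inherits(pp, "pseudo_population")) pp$z else pp$z
  idx <- bins_in_window(pp$time_axis, pp$bin_ms, window)
  d <- dim(z)
  # samples = (trial, bin) pairs, variables = neurons
  X <- t(matrix(z[, idx, , drop = FALSE], nrow = d[1]))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  # numerical rank cutoff so threshold = 1 returns the data rank
  rank <- sum(ev > ev[1] * 1e-12)
  k <- min(which(cumsum(frac) >= variance_threshold - 1e-12), rank)
  structure(list(loadings = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 center = pc$center,
                 explained_variance_fractions = frac,
                 n_components = k,
                 fit_window = window),
            class = "full_space")
}

#' @export
print.full_space <- function(x, ...) {
  cat(sprintf("full_space: %d components (%.1f%% variance) over %d neurons\n",
              x$n_components,
              100 * sum(x$explained_variance_fractions[seq_len(x$n_components)]),
              ncol(x$loadings)))
  invisible(x)
}

#' Project pseudo-population activity onto the full space
#'
#' @param pp A `pseudo_population`.
#' @param fullspace A [fit_full_space()] result.
#' @return A list like `pp` but with `z` replaced by the `n_components x
#'   bins x pseudo-trials` projection.
#' @export
project_full_space <- function(pp, fullspace) {
  stopifnot(inherits(fullspace, "full_space"))
  d <- dim(pp$z)
  flat <- matrix(pp$z, nrow = d[1])           # neurons x (bins*trials)
  proj <- fullspace$loadings %*% (flat - fullspace$center)
  out <- pp
  out$z <- array(proj, dim = c(fullspace$n_components, d[2], d[3]))
  out$space <- "full"
  out
}

#' Build the Delay-1 / Delay-2 matrices for the subspace optimization
#'
#' Each column is one pseudo-trial's activity averaged over the last 500 ms
#' of Delay 1 (`D1`) or a matched Delay 2 window (`D2`), projected onto the
#' full space; columns are grouped by target location. `D1_av` / `D2_av`
#' subtract the mean column of the respective delay, so their Frobenius norm
#' measures between-location (memory) structure.
#'
#' @param proj A full-space-projected `pseudo_population`
#'   (see [project_full_space()]); may also be raw `pseudo_population`
#'   together with `fullspace`.
#' @param fullspace Optional [fit_full_space()]; required if `proj` is not
#'   yet projected.
#' @param d1_window,d2_window `[start, end)` ms windows (defaults
#'   `c(800, 1300)` and `c(1800, 2300)`).
#' @return An object of class `delay_matrices` with `D1`, `D2`, `D1_av`,
#'   `D2_av` (`n_components x (locations * responses)`), `location_labels`,
#'   `windows`.
#' @export
build_delay_matrices <- function(proj, fullspace = NULL,
                                 d1_window = c(800, 1300),
                                 d2_window = c(1800, 2300)) {
  if (!is.null(fullspace) && is.null(proj$space))
    proj <- project_full_space(proj, fullspace)
  i1 <- bins_in_window(proj$time_axis, proj$bin_ms, d1_window)
  i2 <- bins_in_window(proj$time_axis, proj$bin_ms, d2_window)
  avg <- function(idx) apply(proj$z[, idx, , drop = FALSE], c(1, 3), mean)
  ord <- order(match(proj$labels, sort(unique(proj$labels))))
  D1 <- avg(i1)[, ord, drop = FALSE]
  D2 <- avg(i2)[, ord, drop = FALSE]
  labels <- proj$labels[ord]
  structure(list(D1 = D1, D2 = D2,
                 D1_av = D1 - rowMeans(D1),
                 D2_av = D2 - rowMeans(D2),
                 location_labels = labels,
                 windows = list(d1 = d1_window, d2 = d2_window)),
            class = "delay_matrices")
}

#' @export
print.delay_matrices <- function(x, ...) {
  cat(sprintf("delay_matrices: %d x %d (%d locations)\n",
              nrow(x$D1), ncol(x$D1), length(unique(x$location_labels))))
  invisible(x)
}
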
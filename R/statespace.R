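#' Cluster-shift statistics in state space
#'
#' Quantifies how far the per-location cluster centers move between Delay 1
#' and Delay 2, relative to (i) the shift expected within a delay and (ii)
#' the intra-cluster spread. Per bootstrap resample of pseudo-trials (drawn
#' with replacement within each location):
#'
#' * `inter_delay` — mean over locations of the Euclidean distance between
#'   the Delay-1 and Delay-2 window centers;
#' * `d1_to_distractor` — same between Delay 1 and the distractor window;
#' * `intra_delay` — distance between the centers of the first and last
#'   250 ms of each full delay period, averaged over locations and the two
#'   delays (a drift control spanning nearly the same time separation as the
#'   inter-delay comparison);
#' * `normalizer` — mean distance of trial points to their own cluster
#'   center across all `2 * n_locations` clusters;
#'
#' and the `normalized_*` variants divide by `normalizer`, making them
#' invariant to global scaling of the space.
#'
#' @param proj A projected `pseudo_population` (full space or subspace).
#' @param d1_window,d2_window Windows (ms) whose time-averaged activity
#'   defines the Delay-1/Delay-2 cluster centers (defaults: last 500 ms of
#'   Delay 1 and the matched Delay-2 window).
#' @param distractor_window Distractor window (ms).
#' @param delay1_period,delay2_period The full delay epochs (ms) whose first
#'   and last 250 ms define the intra-delay drift control; must span at least
#'   500 ms.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return An object of class `shift_stats` with the raw and normalized
#'   bootstrap distributions.
#' @export
cluster_shift_stats <- function(proj, d1_window = c(800, 1300),
                                d2_window = c(1800, 2300),
                                distractor_window = c(1300, 1600),
                                delay1_period = c(300, 1300),
                                delay2_period = c(1600, 2600),
                                n_boot = 1000L, seed) {
  if (diff(delay1_period) < 500 || diff(delay2_period) < 500)
    stop("delay periods must span at least 500 ms (early/late 250 ms windows)",
         call. = FALSE)
  labels <- proj$labels
  locs <- sort(unique(labels))
  if (any(table(labels) < 2L))
    stop("each location needs at least 2 pseudo-trials", call. = FALSE)
  halves <- function(w) list(c(w[1], w[1] + 250), c(w[2] - 250, w[2]))
  wins <- list(d1 = d1_window, d2 = d2_window, dist = distractor_window,
               d1_early = halves(delay1_period)[[1]],
               d1_late = halves(delay1_period)[[2]],
               d2_early = halves(delay2_period)[[1]],
               d2_late = halves(delay2_period)[[2]])
  # per-window, per-trial time-averaged points (dims x trials), computed once
  pts <- lapply(wins, function(w) {
    idx <- bins_in_window(proj$time_axis, proj$bin_ms, w)
    apply(proj$z[, idx, , drop = FALSE], c(1, 3), mean)
  })
  loc_idx <- lapply(locs, function(l) which(labels == l))
  dists <- function(A, B) sqrt(colSums((A - B)^2))

  out <- list(inter_delay = numeric(n_boot), d1_to_distractor = numeric(n_boot),
              intra_delay = numeric(n_boot), normalizer = numeric(n_boot))
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      picks <- lapply(loc_idx, function(ix) sample(ix, length(ix), replace = TRUE))
      centers <- lapply(pts, function(P)
        vapply(picks, function(ix) rowMeans(P[, ix, drop = FALSE]),
               numeric(nrow(P))))
      out$inter_delay[b] <- mean(dists(centers$d1, centers$d2))
      out$d1_to_distractor[b] <- mean(dists(centers$d1, centers$dist))
      out$intra_delay[b] <- mean(c(dists(centers$d1_early, centers$d1_late),
                                   dists(centers$d2_early, centers$d2_late)))
      spread <- unlist(lapply(c("d1", "d2"), function(w) {
        vapply(seq_along(picks), function(li) {
          P <- pts[[w]][, picks[[li]], drop = FALSE]
          mean(sqrt(colSums((P - centers[[w]][, li])^2)))
        }, numeric(1))
      }))
      out$normalizer[b] <- mean(spread)
    }
  })
  structure(c(out,
              list(normalized_inter_delay = out$inter_delay / out$normalizer,
                   normalized_d1_to_distractor = out$d1_to_distractor / out$normalizer,
                   normalized_intra_delay = out$intra_delay / out$normalizer,
                   n_boot = as.integer(n_boot),
                   space_tag = proj$space %||% "full")),
            class = "shift_stats")
}

#' @export
print.shift_stats <- function(x, ...) {
  cat(sprintf("shift_stats [%s], %d bootstraps\n", x$space_tag, x$n_boot))
  for (nm in c("normalized_inter_delay", "normalized_d1_to_distractor",
               "normalized_intra_delay")) {
    q <- stats::quantile(x[[nm]], c(0.025, 0.975))
    cat(sprintf("  %-28s mean %.3f  [%.3f, %.3f]\n", nm, mean(x[[nm]]), q[1], q[2]))
  }
  invisible(x)
}

#' Trajectory-parallelism magnitude (PLV)
#'
#' For each location, the displacement vector from its Delay-1 center to its
#' Delay-2 center is normalized to unit length; the magnitude of the mean of
#' those unit vectors is returned. 1 indicates perfectly parallel trajectories
#' and 0 complete cancellation. Zero-displacement locations are skipped with
#' a warning.
#'
#' @param centers_d1,centers_d2 `dims x locations` matrices of cluster
#'   centers.
#' @return The PLV value in \[0, 1\].
#' @export
trajectory_plv <- function(centers_d1, centers_d2) {
  stopifnot(is.matrix(centers_d1), identical(dim(centers_d1), dim(centers_d2)))
  if (ncol(centers_d1) < 2L) stop("need at least 2 locations", call. = FALSE)
  V <- centers_d2 - centers_d1
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) {
    warning("zero displacement for ", sum(nrm == 0), " location(s); skipped")
    V <- V[, nrm > 0, drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  U <- sweep(V, 2, nrm, "/")
  sqrt(sum(rowMeans(U)^2))
}

#' Bootstrap distribution of the trajectory PLV
#'
#' Resamples pseudo-trials with replacement within each location, recomputes
#' the Delay-1 and Delay-2 centers, and evaluates [trajectory_plv()].
#'
#' @inheritParams cluster_shift_stats
#' @return An object of class `plv_stat`: `plv` (bootstrap distribution),
#'   `n_vectors`, `space_tag`.
#' @export
plv_bootstrap <- function(proj, d1_window = c(800, 1300),
                          d2_window = c(1800, 2300), n_boot = 1000L, seed) {
  labels <- proj$labels
  locs <- sort(unique(labels))
  pt <- function(w) {
    idx <- bins_in_window(proj$time_axis, proj$bin_ms, w)
    apply(proj$z[, idx, , drop = FALSE], c(1, 3), mean)
  }
  P1 <- pt(d1_window); P2 <- pt(d2_window)
  loc_idx <- lapply(locs, function(l) which(labels == l))
  plv <- numeric(n_boot)
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      picks <- lapply(loc_idx, function(ix) sample(ix, length(ix), replace = TRUE))
      C1 <- vapply(picks, function(ix) rowMeans(P1[, ix, drop = FALSE]),
                   numeric(nrow(P1)))
      C2 <- vapply(picks, function(ix) rowMeans(P2[, ix, drop = FALSE]),
                   numeric(nrow(P2)))
      plv[b] <- suppressWarnings(trajectory_plv(C1, C2))
    }
  })
  structure(list(plv = plv, n_vectors = length(locs), n_boot = as.integer(n_boot),
                 space_tag = proj$space %||% "full"),
            class = "plv_stat")
}

#' @export
print.plv_stat <- function(x, ...) {
  q <- stats::quantile(x$plv, c(0.025, 0.975))
  cat(sprintf("plv_stat [%s]: mean %.3f [%.3f, %.3f] over %d bootstraps (%d vectors)\n",
              x$space_tag, mean(x$plv), q[1], q[2], x$n_boot, x$n_vectors))
  invisible(x)
}
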
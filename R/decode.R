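# --- Regularized linear discriminant classifier (internal) ------------------
#
# Pooled within-class covariance LDA with optional shrinkage toward a scaled
# identity, for the regime where dimensionality is comparable to the per-class
# trial count. shrinkage = "auto" engages lambda = p / (2n) when the training
# sample is smaller than 5x the dimension; "none" disables it (exact LDA);
# a numeric value in [0, 1] is used as-is.
lda_fit <- function(X, y, shrinkage = "auto") {
  classes <- sort(unique(y))
  p <- ncol(X)
  n <- nrow(X)
  M <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                numeric(p)))
  S <- matrix(0, p, p)
  for (ki in seq_along(classes)) {
    Xi <- X[y == classes[ki], , drop = FALSE]
    Xi <- sweep(Xi, 2, M[ki, ])
    S <- S + crossprod(Xi)
  }
  S <- S / max(1, n - length(classes))
  lambda <- if (identical(shrinkage, "auto")) {
    if (n < 5 * p) min(1, p / (2 * n)) else 0
  } else if (identical(shrinkage, "none")) 0 else shrinkage
  if (lambda > 0) {
    mu <- mean(diag(S))
    S <- (1 - lambda) * S + lambda * mu * diag(p)
  }
  B <- tryCatch(solve(S, t(M)), error = function(e) {
    # singular pooled covariance: fall back to a pseudo-inverse
    MASS::ginv(S) %*% t(M)
  })
  list(B = B, const = -0.5 * colSums(t(M) * B), classes = classes)
}

# Predict class indices (into fit$classes); posterior ties broken by lowest
# class index for determinism.
lda_predict <- function(fit, X) {
  scores <- X %*% fit$B + rep(fit$const, each = nrow(X))
  max.col(scores, ties.method = "first")
}

#' Cross-temporal population decoding
#'
#' Trains a linear discriminant classifier on each training time bin and
#' tests it on every testing bin, over stratified random train/test splits of
#' the pseudo-trials, yielding a train-bin x test-bin accuracy matrix and its
#' per-resample distributions.
#'
#' @param x A projected `pseudo_population`, or a `dims x bins x trials`
#'   array (then `labels`, `time_axis` and `bin_ms` are required).
#' @param labels Per-trial class labels (target locations).
#' @param time_axis,bin_ms Bin start times and width (taken from `x` when it
#'   is a `pseudo_population`).
#' @param train_window,test_window `[start, end)` ms window, or a list of
#'   windows, selecting the train/test bins; `NULL` (default) uses all bins.
#' @param n_resamples Number of stratified train/test resamples (default 200).
#' @param train_frac Fraction of each class's trials used for training
#'   (default 0.8).
#' @param shrinkage Covariance shrinkage: `"auto"`, `"none"`, or a value in
#'   \[0, 1\] (see Details in the package vignette).
#' @param seed Integer seed.
#' @param space_tag Label recorded on the result (`"full"`, `"subspace"`,
#'   `"null"`, `"baseline"`).
#' @return An object of class `cross_temporal`: `accuracy` (train x test,
#'   averaged over resamples), `acc_resamples` (train x test x resample),
#'   `train_times`, `test_times`, `bin_ms`, `chance`, `space_tag`.
#' @export
cross_temporal_decode <- function(x, labels = NULL, time_axis = NULL,
                                  bin_ms = NULL, train_window = NULL,
                                  test_window = NULL, n_resamples = 200L,
                                  train_frac = 0.8, shrinkage = "auto",
                                  seed, space_tag = "full") {
  if (is.list(x) && !is.null(x$z)) {
    labels <- labels %||% x$labels
    time_axis <- time_axis %||% x$time_axis
    bin_ms <- bin_ms %||% x$bin_ms
    if (!is.null(x$space)) space_tag <- x$space
    x <- x$z
  }
  stopifnot(is.array(x), length(dim(x)) == 3L, !is.null(labels),
            !is.null(time_axis))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) stop("need at least 2 trials per class", call. = FALSE)

  window_bins <- function(w) {
    if (is.null(w)) return(seq_along(time_axis))
    if (!is.list(w)) w <- list(w)
    sort(unique(unlist(lapply(w, bins_in_window, time_axis = time_axis,
                              bin_ms = bin_ms))))
  }
  train_bins <- window_bins(train_window)
  test_bins <- window_bins(test_window %||% train_window)
  p <- dim(x)[1]
  nB <- length(test_bins)
  acc <- array(NA_real_,
               dim = c(length(train_bins), nB, n_resamples))

  with_local_seed(seed, {
    for (r in seq_len(n_resamples)) {
      train_idx <- integer(0); test_idx <- integer(0)
      for (k in classes) {
        ik <- sample(which(labels == k))
        ntr <- max(1L, floor(train_frac * length(ik)))
        if (ntr >= length(ik)) ntr <- length(ik) - 1L
        train_idx <- c(train_idx, ik[seq_len(ntr)])
        test_idx <- c(test_idx, ik[-seq_len(ntr)])
      }
      y_train <- match(labels[train_idx], classes)
      y_test <- match(labels[test_idx], classes)
      nT <- length(test_idx)
      # stacked test matrix: rows ordered bin-fastest within trial
      Xte <- t(matrix(x[, test_bins, test_idx, drop = FALSE], nrow = p))
      row_bin <- rep(seq_len(nB), times = nT)
      row_lab <- rep(y_test, each = nB)
      for (bi in seq_along(train_bins)) {
        Xtr <- t(matrix(x[, train_bins[bi], train_idx], nrow = p))
        fit <- lda_fit(Xtr, y_train, shrinkage = shrinkage)
        pred <- lda_predict(fit, Xte)
        hit <- as.numeric(fit$classes[pred] == row_lab)
        acc[bi, , r] <- rowsum(hit, row_bin)[, 1] / nT
      }
    }
  })
  structure(list(accuracy = apply(acc, c(1, 2), mean),
                 acc_resamples = acc,
                 train_times = time_axis[train_bins],
                 test_times = time_axis[test_bins],
                 bin_ms = bin_ms,
                 chance = 1 / length(classes),
                 n_resamples = as.integer(n_resamples),
                 space_tag = space_tag),
            class = "cross_temporal")
}

#' @export
print.cross_temporal <- function(x, ...) {
  cat(sprintf("cross_temporal [%s]: %d train x %d test bins, %d resamples, chance %.3f\n",
              x$space_tag, nrow(x$accuracy), ncol(x$accuracy), x$n_resamples,
              x$chance))
  invisible(x)
}

#' LP summary statistics of a cross-temporal matrix
#'
#' Window-averaged cross-temporal accuracies: `lp11` averages cells with
#' train and test bins inside the Delay-1 window, `lp12` train-in-Delay-1 /
#' test-in-Delay-2, and analogously `lp22`, `lp21`; all are per-resample
#' distributions, and the paired differences `lp11 - lp12` and `lp22 - lp21`
#' quantify code-morphing (values above zero) versus time-invariance (values
#' straddling zero).
#'
#' @param ct A [cross_temporal_decode()] result whose bins cover both
#'   windows.
#' @param d1_window,d2_window `[start, end)` ms windows.
#' @return An object of class `lp_stats` with distributions `lp11`, `lp12`,
#'   `lp22`, `lp21`, `diff_11_12`, `diff_22_21`, plus `chance` and
#'   `space_tag`.
#' @export
lp_statistics <- function(ct, d1_window = c(800, 1300),
                          d2_window = c(1800, 2300)) {
  stopifnot(inherits(ct, "cross_temporal"))
  sel <- function(times, w) which(times >= w[1] & (times + ct$bin_ms) <= w[2])
  tr1 <- sel(ct$train_times, d1_window); tr2 <- sel(ct$train_times, d2_window)
  te1 <- sel(ct$test_times, d1_window); te2 <- sel(ct$test_times, d2_window)
  if (!length(tr1) || !length(tr2) || !length(te1) || !length(te2))
    stop("delay windows must each cover at least one train and test bin",
         call. = FALSE)
  blk <- function(tr, te)
    apply(ct$acc_resamples[tr, te, , drop = FALSE], 3, mean)
  lp11 <- blk(tr1, te1); lp12 <- blk(tr1, te2)
  lp22 <- blk(tr2, te2); lp21 <- blk(tr2, te1)
  structure(list(lp11 = lp11, lp12 = lp12, lp22 = lp22, lp21 = lp21,
                 diff_11_12 = lp11 - lp12, diff_22_21 = lp22 - lp21,
                 chance = ct$chance, space_tag = ct$space_tag),
            class = "lp_stats")
}

#' @export
print.lp_stats <- function(x, ...) {
  cat(sprintf("lp_stats [%s] (chance %.3f)\n", x$space_tag, x$chance))
  for (nm in c("lp11", "lp12", "lp22", "lp21", "diff_11_12", "diff_22_21")) {
    q <- stats::quantile(x[[nm]], c(0.025, 0.975))
    cat(sprintf("  %-10s mean %.3f  [%.3f, %.3f]\n", nm, mean(x[[nm]]),
                q[1], q[2]))
  }
  invisible(x)
}

#' Locations with enough error trials for the error analysis
#'
#' Returns the target locations with at least `min_errors_per_session` error
#' trials in *every* session of the trial table.
#'
#' @param trial_table Data frame with `target_loc`, `session`, `correct`.
#' @param min_errors_per_session Threshold (default 6).
#' @return Integer vector of locations (possibly empty, with a message).
#' @export
filter_error_locations <- function(trial_table, min_errors_per_session = 6L) {
  err <- trial_table[!trial_table$correct, , drop = FALSE]
  sessions <- unique(trial_table$session)
  locs <- sort(unique(trial_table$target_loc))
  ok <- vapply(locs, function(l) {
    all(vapply(sessions, function(s)
      sum(err$target_loc == l & err$session == s), integer(1)) >=
        min_errors_per_session)
  }, logical(1))
  out <- locs[ok]
  if (length(out) == 0L)
    message("no analyzable error locations (threshold ",
            min_errors_per_session, " per session)")
  out
}

#' Correct-versus-error decoding in multiple spaces
#'
#' Trains per-bin discriminant decoders on correct pseudo-trials and tests
#' them on held-out correct trials and on error trials, in the full space,
#' the optimized subspace, and its null space. Accuracies are averaged over
#' all (train, test) delay-window cells; the output is the per-resample
#' paired difference (correct minus error) in each space.
#'
#' @param proj_correct,proj_error Full-space-projected `pseudo_population`s
#'   of correct and error trials (same locations and full space).
#' @param map A `subspace_map` fit on the correct trials.
#' @param d1_window,d2_window Delay analysis windows (ms).
#' @param n_resamples,train_frac,shrinkage As in [cross_temporal_decode()].
#' @param seed Integer seed.
#' @return List per space (`full`, `subspace`, `null`) with `diff`
#'   (distribution of accuracy differences), `acc_correct`, `acc_error`, and
#'   the shared `chance` level.
#' @export
error_trial_performance <- function(proj_correct, proj_error, map,
                                    d1_window = c(800, 1300),
                                    d2_window = c(1800, 2300),
                                    n_resamples = 200L, train_frac = 0.8,
                                    shrinkage = "auto", seed) {
  stopifnot(identical(sort(unique(proj_correct$labels)),
                      sort(unique(proj_error$labels))))
  V <- null_space_basis(map)
  spaces <- list(full = diag(dim(proj_correct$z)[1]),
                 subspace = map$U,
                 null = unclass(V))
  classes <- sort(unique(proj_correct$labels))
  chance <- 1 / length(classes)
  res <- lapply(names(spaces), function(sp) {
    P <- spaces[[sp]]
    zc <- project_tensor(proj_correct, P, sp)
    ze <- project_tensor(proj_error, P, sp)
    wb <- function(tens, w) bins_in_window(tens$time_axis, tens$bin_ms, w)
    train_bins <- c(wb(zc, d1_window), wb(zc, d2_window))
    test_bins <- train_bins
    p <- dim(zc$z)[1]
    nB <- length(test_bins)
    acc_c <- numeric(n_resamples); acc_e <- numeric(n_resamples)
    with_local_seed(stage_seed(seed, match(sp, names(spaces))), {
      for (r in seq_len(n_resamples)) {
        tr <- integer(0); ho <- integer(0); er <- integer(0)
        replaced <- FALSE
        for (k in classes) {
          ik <- sample(which(zc$labels == k))
          ntr <- max(1L, min(length(ik) - 1L, floor(train_frac * length(ik))))
          tr <- c(tr, ik[seq_len(ntr)])
          hk <- ik[-seq_len(ntr)]
          ho <- c(ho, hk)
          pool <- which(ze$labels == k)
          if (length(pool) < length(hk)) replaced <- TRUE
          er <- c(er, sample(pool, length(hk),
                             replace = length(pool) < length(hk)))
        }
        eval_set <- function(z, idx, lab) {
          X <- t(matrix(z[, test_bins, idx, drop = FALSE], nrow = p))
          row_lab <- rep(match(lab[idx], classes), each = nB)
          hits <- 0; cells <- 0
          for (b in train_bins) {
            Xtr <- t(matrix(zc$z[, b, tr], nrow = p))
            fit <- lda_fit(Xtr, match(zc$labels[tr], classes), shrinkage)
            pred <- lda_predict(fit, X)
            hits <- hits + sum(fit$classes[pred] == row_lab)
            cells <- cells + length(row_lab)
          }
          hits / cells
        }
        acc_c[r] <- eval_set(zc$z, ho, zc$labels)
        acc_e[r] <- eval_set(ze$z, er, ze$labels)
      }
    })
    list(diff = acc_c - acc_e, acc_correct = acc_c, acc_error = acc_e)
  })
  names(res) <- names(spaces)
  res$chance <- chance
  res
}
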
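#' Subspace optimization cost
#'
#' The objective minimized to find the time-invariant memory subspace:
#' \deqn{\|U(D_1 - D_2)\|_F - \frac{\beta}{2}\left(\|U D_1^{av}\|_F +
#'   \|U D_2^{av}\|_F\right)}
#' The first term pulls corresponding Delay-1 and Delay-2 responses together
#' in the projection; the two mean-subtracted terms reward between-location
#' (memory) variance, weighted by `beta`.
#'
#' Note the objective is positively homogeneous of degree 1 in `U`
#' (`cost(cU) = c * cost(U)` for `c > 0`), so the raw problem is
#' scale-degenerate; see [optimize_subspace()] for how that is handled.
#'
#' @param U `u_dim x n_components` projection matrix.
#' @param dm A [build_delay_matrices()] result.
#' @param beta Information weight (default 0.1).
#' @return The scalar cost.
#' @export
subspace_cost <- function(U, dm, beta = 0.1) {
  stopifnot(inherits(dm, "delay_matrices"))
  if (ncol(U) != nrow(dm$D1)) stop("U and delay matrices are not conformable",
                                   call. = FALSE)
  frobenius(U %*% (dm$D1 - dm$D2)) -
    (beta / 2) * (frobenius(U %*% dm$D1_av) + frobenius(U %*% dm$D2_av))
}

# Analytic gradient of subspace_cost. d||UA||_F/dU = (UA)A' / ||UA||_F, with
# the zero subgradient used at exactly-zero norms.
subspace_cost_grad <- function(U, dm, beta = 0.1) {
  term <- function(A, w) {
    UA <- U %*% A
    nrm <- sqrt(sum(UA * UA))
    if (nrm == 0) return(matrix(0, nrow(U), ncol(U)))
    w * (UA %*% t(A)) / nrm
  }
  term(dm$D1 - dm$D2, 1) + term(dm$D1_av, -beta / 2) + term(dm$D2_av, -beta / 2)
}

#' Identify the time-invariant subspace
#'
#' Minimizes [subspace_cost()] with a quasi-Newton (BFGS) iteration from a
#' seeded random start (`U` i.i.d. uniform in \[-0.5, 0.5\]), using the
#' analytic Frobenius-norm gradient, an iteration cap, and multi-start
#' (best of `n_starts`). In the default unconstrained mode — mirroring the
#' original unconstrained formulation — a candidate solution is accepted only
#' if its Frobenius norm stays within \[0.1, 10\] times the initial norm,
#' guarding against the scale degeneracy of the objective; the optional
#' `constraint = "row-norm"` mode instead evaluates the cost on row-normalized
#' `U`, which removes the degeneracy altogether.
#'
#' @param dm A [build_delay_matrices()] result.
#' @param beta Information weight (default 0.1).
#' @param u_dim Subspace dimensionality (default 8; must be below the number
#'   of full-space components).
#' @param seed Integer seed for the random initializations.
#' @param n_starts Number of random restarts (default 5).
#' @param maxit Iteration cap per start (default 500).
#' @param constraint `"none"` (default; the original unconstrained
#'   formulation) or `"orthonormal"` (rows of `U` constrained to an
#'   orthonormal set, which removes the scale degeneracy and prevents rank
#'   collapse; optimized by projected gradient descent with QR retraction).
#' @return An object of class `subspace_map`: `U`, `beta`, `u_dim`, `cost`,
#'   `cost_trace` (best cost seen after each objective evaluation),
#'   `converged`, `constraint`, `init_seed`, `n_starts`.
#' @export
optimize_subspace <- function(dm, beta = 0.1, u_dim = 8L, seed,
                              n_starts = 5L, maxit = 500L,
                              constraint = c("none", "orthonormal")) {
  stopifnot(inherits(dm, "delay_matrices"), u_dim >= 1L)
  constraint <- match.arg(constraint)
  n_comp <- nrow(dm$D1)
  if (u_dim >= n_comp)
    stop("u_dim must be smaller than the number of full-space components",
         call. = FALSE)

  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_starts)) {
      U0 <- matrix(stats::runif(u_dim * n_comp, -0.5, 0.5), u_dim, n_comp)
      fit <- if (constraint == "orthonormal")
        optimize_stiefel(U0, dm, beta, maxit)
      else
        optimize_bfgs(U0, dm, beta, maxit)
      if (is.null(fit) || !is.finite(fit$cost)) next
      if (is.null(best) ||
          (fit$accepted && !best$accepted) ||
          (fit$accepted == best$accepted && fit$cost < best$cost))
        best <- fit
    }
  })
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  structure(list(U = best$U, beta = beta, u_dim = as.integer(u_dim),
                 cost = best$cost, cost_trace = best$cost_trace,
                 converged = best$converged, constraint = constraint,
                 init_seed = as.integer(seed), n_starts = as.integer(n_starts)),
            class = "subspace_map")
}

#' @export
print.subspace_map <- function(x, ...) {
  cat(sprintf("subspace_map: %d x %d, beta = %g, cost = %.4g (%s, %s)\n",
              nrow(x$U), ncol(x$U), x$beta, x$cost,
              if (x$converged) "converged" else "not converged",
              x$constraint))
  invisible(x)
}

# Unconstrained quasi-Newton minimization (the original formulation). The
# degree-1 homogeneity of the cost makes the raw problem scale-degenerate:
# depending on the data it is either minimized at U = 0 or unbounded below
# along an information-rich morph-free ray. A candidate is accepted only if
# its Frobenius norm stays within [0.1, 10] of the initial norm.
optimize_bfgs <- function(U0, dm, beta, maxit) {
  u_dim <- nrow(U0); n_comp <- ncol(U0)
  init_norm <- frobenius(U0)
  trace_env <- new.env(); trace_env$tr <- numeric(0)
  fn <- function(par) {
    v <- subspace_cost(matrix(par, u_dim, n_comp), dm, beta)
    if (!is.finite(v)) return(1e30)
    trace_env$tr <- c(trace_env$tr,
                      if (length(trace_env$tr)) min(v, min(trace_env$tr)) else v)
    v
  }
  gr <- function(par)
    as.vector(subspace_cost_grad(matrix(par, u_dim, n_comp), dm, beta))
  fit <- tryCatch(
    stats::optim(as.vector(U0), fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  U <- matrix(fit$par, u_dim, n_comp)
  ratio <- frobenius(U) / init_norm
  ok <- ratio >= 0.1 && ratio <= 10
  list(U = U, cost = fit$value, converged = fit$convergence == 0 && ok,
       accepted = ok, cost_trace = trace_env$tr)
}

# Row-orthonormalize by QR of the transpose, with sign correction so the
# retraction is continuous in its argument.
qr_orth_rows <- function(U) {
  qrd <- qr(t(U))
  Q <- qr.Q(qrd)
  sgn <- sign(diag(qr.R(qrd)))
  sgn[sgn == 0] <- 1
  t(Q * rep(sgn, each = nrow(Q)))
}

# Projected gradient descent on the Stiefel manifold {U : U U' = I} with QR
# retraction and backtracking line search.
optimize_stiefel <- function(U0, dm, beta, maxit, tol = 1e-9) {
  U <- qr_orth_rows(U0)
  cost <- subspace_cost(U, dm, beta)
  tr <- cost
  step <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    G <- subspace_cost_grad(U, dm, beta)
    # tangent-space projection for row-orthonormal U: G - sym(G U') U
    GU <- G %*% t(U)
    Gt <- G - 0.5 * (GU + t(GU)) %*% U
    gnorm <- frobenius(Gt)
    if (gnorm < tol * max(1, abs(cost))) { converged <- TRUE; break }
    improved <- FALSE
    for (ls in 1:30) {
      U_new <- qr_orth_rows(U - step * Gt)
      cost_new <- subspace_cost(U_new, dm, beta)
      if (is.finite(cost_new) && cost_new < cost - 1e-12 * abs(cost)) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    U <- U_new
    cost <- cost_new
    tr <- c(tr, cost)
    step <- step * 1.5
  }
  list(U = U, cost = cost, converged = converged, accepted = TRUE,
       cost_trace = tr)
}

#' Project full-space data into the subspace
#'
#' @param map A `subspace_map` (or any list with a matrix element `U`).
#' @param X `n_components x columns` matrix.
#' @return `u_dim x columns` matrix `U %*% X`.
#' @export
project_subspace <- function(map, X) {
  U <- if (is.matrix(map)) map else map$U
  if (ncol(U) != nrow(X)) stop("shape mismatch in project_subspace", call. = FALSE)
  U %*% X
}

#' Project a full-space pseudo-population tensor through a projection matrix
#'
#' @param proj A full-space-projected `pseudo_population`.
#' @param U Projection matrix (`k x n_components`), e.g. `map$U` or a null
#'   basis `V`.
#' @param space_tag Label stored on the result (`"subspace"`, `"null"`, ...).
#' @return The `pseudo_population` with `z` replaced by the projection.
#' @export
project_tensor <- function(proj, U, space_tag = "subspace") {
  if (!is.matrix(U)) U <- U$U
  d <- dim(proj$z)
  if (ncol(U) != d[1]) stop("shape mismatch in project_tensor", call. = FALSE)
  out <- proj
  out$z <- array(U %*% matrix(proj$z, nrow = d[1]),
                 dim = c(nrow(U), d[2], d[3]))
  out$space <- space_tag
  out
}

#' Orthonormal basis of the null space of the subspace projection
#'
#' Returns a `(n_components - rank(U)) x n_components` matrix `V` with
#' orthonormal rows satisfying `U %*% t(V) = 0`: the full-space directions
#' invisible to the subspace readout.
#'
#' @param map A `subspace_map` or projection matrix.
#' @return An object of class `null_basis` (a matrix `V` with attribute
#'   `rank`).
#' @export
null_space_basis <- function(map) {
  U <- if (is.matrix(map)) map else map$U
  r <- qr(U)$rank
  if (r < nrow(U))
    warning("U is rank deficient (rank ", r, " < ", nrow(U),
            "); null space enlarged accordingly")
  N <- MASS::Null(t(U))                     # columns span {v : U v = 0}
  V <- t(N)
  structure(V, rank = r, class = c("null_basis", class(V)))
}

#' Per-neuron contribution weights of the subspace
#'
#' Multiplies the subspace map by the PCA loadings to express the subspace
#' directly in neuron coordinates, takes entrywise magnitudes, normalizes by
#' the single largest weight, and averages over subspace dimensions to give
#' one weight in \[0, 1\] per neuron.
#'
#' @param map A `subspace_map`.
#' @param fullspace A [fit_full_space()] result.
#' @return Numeric vector, one weight per neuron.
#' @export
neuron_contributions <- function(map, fullspace) {
  U <- if (is.matrix(map)) map else map$U
  if (ncol(U) != nrow(fullspace$loadings))
    stop("subspace and full space are not conformable", call. = FALSE)
  W <- abs(U %*% fullspace$loadings)
  mx <- max(W)
  if (mx == 0) stop("degenerate subspace: all contribution weights are zero",
                    call. = FALSE)
  colMeans(W / mx)
}

#' Cumulative variance curve inside the subspace
#'
#' Concatenates the projected Delay-1 and Delay-2 matrices (`u_dim x
#' 2*columns`) and re-runs PCA on the result, returning the cumulative
#' explained-variance fraction per subspace dimension.
#'
#' @param map A `subspace_map`.
#' @param dm A [build_delay_matrices()] result.
#' @return Non-decreasing numeric vector ending at 1.
#' @export
subspace_variance_curve <- function(map, dm) {
  P <- cbind(project_subspace(map, dm$D1), project_subspace(map, dm$D2))
  if (ncol(P) < nrow(P)) stop("fewer columns than subspace dimensions",
                              call. = FALSE)
  ev <- stats::prcomp(t(P), center = TRUE)$sdev^2
  cumsum(ev) / sum(ev)
}

#' Shuffle Delay-2 location labels of the delay matrices
#'
#' Control analysis: applies a seeded, derangement-preferring permutation to
#' the Delay-2 location blocks (columns move with their labels), leaving
#' Delay 1 untouched and recomputing `D2_av`. Optimizing on the shuffled
#' matrices should fail to produce a time-invariant memory subspace.
#'
#' @param dm A [build_delay_matrices()] result.
#' @param seed Integer seed.
#' @return A `delay_matrices` object with attribute `"permutation"`.
#' @export
shuffle_delay2_labels <- function(dm, seed) {
  stopifnot(inherits(dm, "delay_matrices"))
  locs <- sort(unique(dm$location_labels))
  if (length(locs) < 2L) stop("need at least 2 locations to shuffle", call. = FALSE)
  perm <- derangement(length(locs), seed)
  new_cols <- integer(length(dm$location_labels))
  for (li in seq_along(locs)) {
    # columns labeled locs[li] take the responses of locs[perm[li]]
    new_cols[dm$location_labels == locs[li]] <-
      which(dm$location_labels == locs[perm[li]])
  }
  out <- dm
  out$D2 <- dm$D2[, new_cols, drop = FALSE]
  out$D2_av <- out$D2 - rowMeans(out$D2)
  attr(out, "permutation") <- perm
  out
}

#' Shuffle Delay-2 activity across locations in a projected tensor
#'
#' Tensor-level counterpart of [shuffle_delay2_labels()]: within the bins at
#' and after `from_ms`, each location's pseudo-trials receive the activity of
#' the permuted location (matched by response index), creating the shuffled
#' dataset used for control decoding and trajectory statistics.
#'
#' @param proj A projected `pseudo_population`.
#' @param from_ms Time (ms) from which activity is swapped (default: 1300,
#'   distractor onset, so Delay-2 and distractor epochs are shuffled while
#'   Delay 1 is intact).
#' @param seed Integer seed (shared with [shuffle_delay2_labels()] semantics).
#' @return The shuffled `pseudo_population`, with attribute `"permutation"`.
#' @export
shuffle_delay2_trials <- function(proj, from_ms = 1300, seed) {
  locs <- sort(unique(proj$labels))
  if (length(locs) < 2L) stop("need at least 2 locations to shuffle", call. = FALSE)
  perm <- derangement(length(locs), seed)
  bins <- which(proj$time_axis >= from_ms)
  out <- proj
  for (li in seq_along(locs)) {
    dst <- which(proj$labels == locs[li])
    src <- which(proj$labels == locs[perm[li]])
    stopifnot(length(dst) == length(src))
    out$z[, bins, dst] <- proj$z[, bins, src]
  }
  attr(out, "permutation") <- perm
  out
}

#' Baseline subspaces for comparison
#'
#' Two standard alternatives to the optimized subspace:
#' `"time_averaged_pca"` — the mnemonic subspace: principal components of the
#' per-location mean, time-averaged delay activity (at most
#' `n_locations - 1` informative axes); `"lda"` — linear discriminant axes of
#' Delay-1-labeled activity (at most `n_locations - 1` axes).
#'
#' @param proj A full-space-projected `pseudo_population`.
#' @param method `"time_averaged_pca"` or `"lda"`.
#' @param u_dim Number of axes to return.
#' @param windows List of `[start, end)` ms windows averaged for the
#'   condition means (default Delay-1 and Delay-2 analysis windows).
#' @return A `subspace_map`-compatible list with the `u_dim x n_components`
#'   projection matrix `U` and `method` metadata.
#' @export
baseline_subspace <- function(proj, method = c("time_averaged_pca", "lda"),
                              u_dim = 6L,
                              windows = list(c(800, 1300), c(1800, 2300))) {
  method <- match.arg(method)
  locs <- sort(unique(proj$labels))
  if (u_dim > length(locs) - 1L)
    stop("u_dim cannot exceed n_locations - 1 for this baseline", call. = FALSE)
  if (method == "time_averaged_pca") {
    idx <- unlist(lapply(windows, bins_in_window,
                         time_axis = proj$time_axis, bin_ms = proj$bin_ms))
    M <- vapply(locs, function(l) {
      rowMeans(apply(proj$z[, idx, proj$labels == l, drop = FALSE],
                     c(1, 3), mean))
    }, numeric(dim(proj$z)[1]))
    U <- t(stats::prcomp(t(M), center = TRUE)$rotation[, seq_len(u_dim),
                                                       drop = FALSE])
  } else {
    idx <- bins_in_window(proj$time_axis, proj$bin_ms, windows[[1]])
    X <- t(apply(proj$z[, idx, , drop = FALSE], c(1, 3), mean))
    fit <- MASS::lda(X, grouping = factor(proj$labels))
    U <- t(fit$scaling[, seq_len(u_dim), drop = FALSE])
  }
  structure(list(U = unname(U), u_dim = as.integer(u_dim), method = method,
                 beta = NA_real_, cost = NA_real_, converged = TRUE,
                 constraint = "none"),
            class = "subspace_map")
}

#' Held-out-location generalization of the subspace
#'
#' Optimizes the subspace using only a subset of target locations' columns,
#' then measures decoding time-invariance (LP statistics) on the held-out
#' locations projected with that map.
#'
#' @param proj A full-space-projected `pseudo_population`.
#' @param dm Delay matrices built from `proj`.
#' @param train_locations Locations used for the optimization (>= 2).
#' @param beta,u_dim,n_starts See [optimize_subspace()].
#' @param n_resamples,train_frac See [cross_temporal_decode()].
#' @param seed Integer seed.
#' @return List with the fitted `map`, the held-out `lp` statistics
#'   ([lp_statistics()]), and `heldout_locations`.
#' @export
heldout_location_generalization <- function(proj, dm, train_locations,
                                            beta = 0.1, u_dim = 8L,
                                            n_starts = 5L, n_resamples = 100L,
                                            train_frac = 0.8, seed) {
  locs <- sort(unique(dm$location_labels))
  if (length(train_locations) < 2L)
    stop("need at least 2 training locations", call. = FALSE)
  heldout <- setdiff(locs, train_locations)
  if (length(heldout) == 0L) stop("held-out location set is empty", call. = FALSE)
  keep <- dm$location_labels %in% train_locations
  dm_train <- dm
  dm_train$D1 <- dm$D1[, keep, drop = FALSE]
  dm_train$D2 <- dm$D2[, keep, drop = FALSE]
  dm_train$D1_av <- dm_train$D1 - rowMeans(dm_train$D1)
  dm_train$D2_av <- dm_train$D2 - rowMeans(dm_train$D2)
  dm_train$location_labels <- dm$location_labels[keep]
  map <- optimize_subspace(dm_train, beta = beta, u_dim = u_dim,
                           seed = stage_seed(seed, 1L), n_starts = n_starts)
  sel <- proj$labels %in% heldout
  sub <- proj
  sub$z <- proj$z[, , sel, drop = FALSE]
  sub$labels <- proj$labels[sel]
  sub <- project_tensor(sub, map, "subspace")
  ct <- cross_temporal_decode(sub$z, sub$labels,
                              time_axis = sub$time_axis, bin_ms = sub$bin_ms,
                              train_window = c(dm$windows$d1[1], dm$windows$d2[2]),
                              n_resamples = n_resamples, train_frac = train_frac,
                              seed = stage_seed(seed, 2L))
  lp <- lp_statistics(ct, dm$windows$d1, dm$windows$d2)
  list(map = map, lp = lp, heldout_locations = heldout)
}
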
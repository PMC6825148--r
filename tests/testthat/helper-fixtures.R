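# Synthetic fixtures built in code; no stored data.

# A small Gaussian pseudo-population with per-location cluster means that are
# constant over time bins (stationary code), an optional additive shift
# applied from `shift_from_ms` onward (a constructed D1 -> D2 displacement),
# and optional per-location shifts (a matrix dims x locations).
make_gauss_pp <- function(n_dims = 6, locations = 1:4, n_per = 20,
                          noise = 0.1, shift = NULL, shift_from_ms = 1300,
                          separation = 3, seed = 1,
                          time_axis = seq(300, 2500, 50), bin_ms = 100) {
  set.seed(seed)
  mus <- matrix(rnorm(n_dims * length(locations), sd = separation),
                n_dims, length(locations))
  labels <- rep(locations, each = n_per)
  n_tr <- length(labels)
  z <- array(rnorm(n_dims * length(time_axis) * n_tr, sd = noise),
             dim = c(n_dims, length(time_axis), n_tr))
  for (tr in seq_len(n_tr)) {
    li <- match(labels[tr], locations)
    z[, , tr] <- z[, , tr] + mus[, li]
    if (!is.null(shift)) {
      late <- which(time_axis >= shift_from_ms)
      s <- if (is.matrix(shift)) shift[, li] else shift
      z[, late, tr] <- z[, late, tr] + s
    }
  }
  structure(list(z = z, labels = labels, time_axis = time_axis,
                 bin_ms = bin_ms, locations = locations, space = "full"),
            class = "pseudo_population")
}

# A tiny population_tensor with prescribed rates (neurons x steps x trials).
make_tensor <- function(rates, t0 = -300, step = 50, targets = NULL) {
  d <- dim(rates)
  if (is.null(targets)) targets <- rep_len(1:2, d[3])
  population_tensor(
    rates, seq(t0, by = step, length.out = d[2]),
    data.frame(trial_id = seq_len(d[3]), session = 1L,
               target_loc = targets,
               distractor_loc = targets %% 8 + 1L, correct = TRUE),
    bin_ms = step)
}

# Delay matrices assembled directly from given D1/D2 (bypassing the tensor
# path) for optimizer unit tests.
make_dm <- function(D1, D2, labels) {
  structure(list(D1 = D1, D2 = D2,
                 D1_av = D1 - rowMeans(D1), D2_av = D2 - rowMeans(D2),
                 location_labels = labels,
                 windows = list(d1 = c(800, 1300), d2 = c(1800, 2300))),
            class = "delay_matrices")
}

# Brute-force Frobenius norm (loop-based oracle, independent of the package's
# vectorized implementation).
frob_oracle <- function(M) {
  s <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) s <- s + M[i, j]^2
  sqrt(s)
}

# Small bump configuration for structural tests (fast, 4 locations).
small_bump_cfg <- function(...) {
  bump_config(n_units = 32L, n_locations = 4L, units_per_location = 8L,
              nonmemory_units = 4L, ...)
}
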
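#' @keywords internal
"_PACKAGE"

# Run an expression with a local RNG state so package functions are
# reproducible without clobbering the caller's random stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite integer `seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation from a master seed: stage k maps to
# (seed * 101 + k) mod 2^31 - 1, kept strictly below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 101 + stage) %% (2^31 - 1))
}

# Indices of bins whose [start, start + bin_ms) support lies inside the
# half-open window [w1, w2). All window arithmetic in the package is half-open.
bins_in_window <- function(time_axis, bin_ms, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  idx <- which(time_axis >= window[1] & (time_axis + bin_ms) <= window[2])
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g) contains no complete bins", window[1], window[2]),
         call. = FALSE)
  idx
}

frobenius <- function(M) sqrt(sum(M * M))

# FNV-1a hash of a string, returned as 8 hex digits; used to fingerprint
# configurations in report artifacts.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Seeded permutation of 1..n that prefers a derangement (no fixed points);
# falls back to the permutation with fewest fixed points if none is found.
derangement <- function(n, seed, max_tries = 1000L) {
  if (n < 2L) stop("need at least 2 elements to shuffle", call. = FALSE)
  with_local_seed(seed, {
    best <- sample.int(n)
    best_fp <- sum(best == seq_len(n))
    tries <- 1L
    while (best_fp > 0L && tries < max_tries) {
      p <- sample.int(n)
      fp <- sum(p == seq_len(n))
      if (fp < best_fp) {
        best <- p
        best_fp <- fp
      }
      tries <- tries + 1L
    }
    best
  })
}
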
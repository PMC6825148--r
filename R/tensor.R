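#' Trial-structured population rate tensor
#'
#' The common container for simulated (or recorded) population activity:
#' a `neurons x time-bins x trials` array together with the bin start times
#' and a per-trial table of task conditions.
#'
#' @param rates Numeric array `neurons x bins x trials`; all values finite.
#'   The bump-attractor simulator produces non-negative rates; the linear
#'   model is unbounded, so negativity is permitted there.
#' @param time_axis Numeric vector of bin start times (ms relative to target
#'   onset), strictly increasing and uniformly spaced, length `dim(rates)[2]`.
#' @param trial_table Data frame with one row per trial and columns
#'   `trial_id`, `session`, `target_loc` (1..n_locations), `distractor_loc`,
#'   `correct` (logical).
#' @param bin_ms Duration in ms that each bin averages over.
#' @param meta Optional named list of provenance metadata (model config etc.).
#'
#' @return An object of class `population_tensor`.
#' @export
population_tensor <- function(rates, time_axis, trial_table, bin_ms,
                              meta = list()) {
  stopifnot(is.array(rates), length(dim(rates)) == 3L)
  if (!all(is.finite(rates))) stop("rates must be finite", call. = FALSE)
  if (length(time_axis) != dim(rates)[2])
    stop("time_axis length must match the bin dimension", call. = FALSE)
  d <- diff(time_axis)
  if (any(d <= 0) || (length(d) > 1 && max(abs(d - d[1])) > 1e-9))
    stop("time_axis must be strictly increasing and uniform", call. = FALSE)
  req <- c("trial_id", "session", "target_loc", "distractor_loc", "correct")
  if (!all(req %in% names(trial_table)))
    stop("trial_table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(trial_table) != dim(rates)[3])
    stop("trial_table rows must match the trial dimension", call. = FALSE)
  bad <- trial_table$distractor_loc == trial_table$target_loc
  if (any(bad, na.rm = TRUE))
    stop("distractor_loc must differ from target_loc on every trial",
         call. = FALSE)
  structure(list(rates = rates, time_axis = as.numeric(time_axis),
                 trial_table = trial_table, bin_ms = bin_ms, meta = meta),
            class = "population_tensor")
}

#' @export
print.population_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("population_tensor: %d neurons x %d bins (%g ms) x %d trials\n",
              d[1], d[2], x$bin_ms, d[3]))
  cat(sprintf("  time %g..%g ms; %d correct / %d error trials\n",
              min(x$time_axis), max(x$time_axis) + x$bin_ms,
              sum(x$trial_table$correct), sum(!x$trial_table$correct)))
  invisible(x)
}

#' Write / read a population tensor
#'
#' Serializes the rate array and metadata to an R data store (`.rds`) and the
#' trial table to a plain CSV with header
#' `trial_id,session,target_loc,distractor_loc,correct` alongside it.
#'
#' @param x A `population_tensor`.
#' @param path Output path for the array container; the trial table is
#'   written to `<path>_trials.csv`.
#' @return `write_population_tensor` returns `path` invisibly;
#'   `read_population_tensor` returns the restored `population_tensor`.
#' @export
write_population_tensor <- function(x, path) {
  stopifnot(inherits(x, "population_tensor"))
  saveRDS(x[c("rates", "time_axis", "bin_ms", "meta")], path)
  utils::write.csv(x$trial_table,
                   paste0(sub("\\.rds$", "", path), "_trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_tensor
#' @export
read_population_tensor <- function(path) {
  core <- readRDS(path)
  tt <- utils::read.csv(paste0(sub("\\.rds$", "", path), "_trials.csv"))
  tt$correct <- as.logical(tt$correct)
  population_tensor(core$rates, core$time_axis, tt, core$bin_ms, core$meta)
}
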
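#' Task timeline for the delayed-saccade-with-distractor task
#'
#' Defines the epoch structure of a simulated trial: a pre-target baseline,
#' a 300 ms target presentation, a 1000 ms first memory delay (Delay 1), a
#' 300 ms distractor presentation, and a 1000 ms second delay (Delay 2).
#' All windows are half-open `[start, end)` intervals in milliseconds
#' relative to target onset, and must be contiguous and divisible by the
#' simulation step.
#'
#' @param baseline,target,delay1,distractor,delay2 Length-2 numeric vectors
#'   giving `[start, end)` of each epoch in ms.
#' @param extra Optional named list of additional contiguous epochs appended
#'   after `delay2` (used by two-distractor task variants), e.g.
#'   `list(distractor2 = c(2600, 2900), delay3 = c(2900, 3900))`.
#' @param step_ms Simulation step in ms; must divide every window length.
#'
#' @return An object of class `task_timeline`: a named list of windows plus
#'   `step_ms`, `t_start`, `t_end` and the per-step `time_axis` (step start
#'   times).
#' @examples
#' tl <- task_timeline()
#' tl$delay2
#' @export
task_timeline <- function(baseline = c(-300, 0),
                          target = c(0, 300),
                          delay1 = c(300, 1300),
                          distractor = c(1300, 1600),
                          delay2 = c(1600, 2600),
                          extra = NULL,
                          step_ms = 50) {
  windows <- c(list(baseline = baseline, target = target, delay1 = delay1,
                    distractor = distractor, delay2 = delay2), extra)
  for (w in windows) {
    if (length(w) != 2L || w[2] <= w[1])
      stop("each window must be c(start, end) with end > start", call. = FALSE)
  }
  starts <- vapply(windows, `[`, numeric(1), 1L)
  ends <- vapply(windows, `[`, numeric(1), 2L)
  if (any(starts[-1] != ends[-length(ends)]))
    stop("windows must be contiguous and ordered", call. = FALSE)
  if (any((ends - starts) %% step_ms != 0))
    stop("step_ms must divide every window length", call. = FALSE)
  t_start <- starts[1]
  t_end <- ends[length(ends)]
  structure(
    c(windows,
      list(step_ms = step_ms, t_start = t_start, t_end = t_end,
           time_axis = seq(t_start, t_end - step_ms, by = step_ms))),
    class = "task_timeline")
}

#' @export
print.task_timeline <- function(x, ...) {
  nm <- setdiff(names(x), c("step_ms", "t_start", "t_end", "time_axis"))
  cat("Task timeline (", x$step_ms, " ms steps, ",
      length(x$time_axis), " steps)\n", sep = "")
  for (w in nm)
    cat(sprintf("  %-12s [%6g, %6g) ms\n", w, x[[w]][1], x[[w]][2]))
  invisible(x)
}
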
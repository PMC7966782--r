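#' Build the analysis window grid
#'
#' Lays overlapping analysis windows over the pre-seizure span. Seizure onset
#' sits at the end of the span; window `w` covers
#' `[(w - 1) * step, (w - 1) * step + window_len)` seconds from record start
#' and the last window ends at onset. With the defaults (5-min windows,
#' 5-s step) consecutive windows overlap by 98.33%.
#'
#' @param span_min analysed span in minutes (default 240).
#' @param window_len_s window length in seconds (default 300).
#' @param step_s step between window starts in seconds (default 5).
#' @return an object of class `window_grid` with fields `span_min`,
#'   `window_len_s`, `step_s`, `n_windows`, `overlap_pct`.
#' @examples
#' g <- build_window_grid(240, 300, 5)
#' g$n_windows
#' g$overlap_pct
#' @export
build_window_grid <- function(span_min = 240, window_len_s = 300, step_s = 5) {
  stop_if_not_scalar_number(span_min, "span_min")
  stop_if_not_scalar_number(window_len_s, "window_len_s")
  stop_if_not_scalar_number(step_s, "step_s")
  span_s <- span_min * 60
  if (window_len_s > span_s) {
    stop("window_len_s must not exceed the span", call. = FALSE)
  }
  if (step_s <= 0) stop("step_s must be positive", call. = FALSE)
  if (step_s > window_len_s) {
    stop("step_s must not exceed window_len_s (windows must overlap or tile)",
         call. = FALSE)
  }
  n <- floor((span_s - window_len_s) / step_s) + 1L
  structure(
    list(
      span_min = span_min,
      window_len_s = window_len_s,
      step_s = step_s,
      n_windows = as.integer(n),
      overlap_pct = 100 * (1 - step_s / window_len_s)
    ),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "<window_grid> %d windows of %g s at %g-s step over %g min (%.2f%% overlap)\n",
    x$n_windows, x$window_len_s, x$step_s, x$span_min, x$overlap_pct
  ))
  invisible(x)
}

# Window start times in seconds from record start.
window_starts <- function(grid) {
  (seq_len(grid$n_windows) - 1L) * grid$step_s
}

#' Minutes before seizure onset at which each window starts
#'
#' Onset is at the end of the span, so window 1 starts `span_min` minutes
#' before onset and the last window starts `window_len_s / 60` minutes before.
#'
#' @param grid a [build_window_grid()].
#' @param windows optional window indices (default all).
#' @return numeric vector of minutes before onset.
#' @export
window_start_before_onset <- function(grid, windows = seq_len(grid$n_windows)) {
  stopifnot(inherits(grid, "window_grid"))
  (grid$span_min * 60 - (windows - 1L) * grid$step_s) / 60
}
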
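#' RR-interval series
#'
#' Container for a beat-to-beat (RR interval) series: beat times in seconds
#' from record start, the RR durations between consecutive beats, and a
#' per-interval quality flag. Interval `i` spans
#' `[beat_times[i], beat_times[i + 1])`, so there is one fewer interval than
#' beats. Intervals flagged `"excluded"` never enter feature computation;
#' `"corrected"` intervals are interpolated replacements produced by
#' [edit_rri()].
#'
#' @param beat_times numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param rr optional numeric vector of RR intervals in seconds,
#'   `length(beat_times) - 1`. Defaults to `diff(beat_times)`.
#' @param quality character vector of per-interval flags in
#'   `c("valid", "corrected", "excluded")`; recycled from `"valid"`.
#' @return an object of class `rri_series` with fields `beat_times`, `rr`,
#'   `quality`.
#' @examples
#' x <- rri_series(seq(0, 10, by = 0.8))
#' summary(x$rr)
#' @export
rri_series <- function(beat_times, rr = NULL, quality = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && any(!is.finite(beat_times))) {
    stop("beat_times must be finite", call. = FALSE)
  }
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop("beat_times must be strictly increasing", call. = FALSE)
  }
  n_int <- max(length(beat_times) - 1L, 0L)
  if (is.null(rr)) rr <- diff(beat_times)
  rr <- as.numeric(rr)
  if (length(rr) != n_int) {
    stop("rr must have length(beat_times) - 1 elements", call. = FALSE)
  }
  if (n_int && any(rr <= 0)) stop("RR intervals must be positive", call. = FALSE)
  if (is.null(quality)) quality <- rep("valid", n_int)
  quality <- as.character(quality)
  if (length(quality) == 1L) quality <- rep(quality, n_int)
  if (length(quality) != n_int) {
    stop("quality must have one flag per interval", call. = FALSE)
  }
  bad <- setdiff(unique(quality), c("valid", "corrected", "excluded"))
  if (length(bad)) {
    stop("unknown quality flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(beat_times = beat_times, rr = rr, quality = quality),
    class = "rri_series"
  )
}

#' @export
print.rri_series <- function(x, ...) {
  n <- length(x$rr)
  cat(sprintf(
    "<rri_series> %d intervals over %.1f s (mean RR %.3f s; %d corrected, %d excluded)\n",
    n, if (n) diff(range(x$beat_times)) else 0,
    if (n) mean(x$rr) else NA_real_,
    sum(x$quality == "corrected"), sum(x$quality == "excluded")
  ))
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$rr)

#' Write / read an RR-interval series as CSV
#'
#' The on-disk format is one row per interval with columns `beat_time_s` (the
#' time of the beat opening the interval), `rr_s` and `quality`.
#'
#' @param x an [rri_series()].
#' @param path file path.
#' @return `write_rri_csv()` returns `path` invisibly; `read_rri_csv()`
#'   returns an [rri_series()].
#' @export
write_rri_csv <- function(x, path) {
  stopifnot(inherits(x, "rri_series"))
  df <- data.frame(
    beat_time_s = x$beat_times[-length(x$beat_times)],
    rr_s = x$rr,
    quality = x$quality
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rri_csv
#' @export
read_rri_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("beat_time_s", "rr_s")
  if (!all(need %in% names(df))) {
    stop("RRI CSV must contain columns beat_time_s and rr_s", call. = FALSE)
  }
  beat_times <- c(df$beat_time_s, df$beat_time_s[nrow(df)] + df$rr_s[nrow(df)])
  quality <- if ("quality" %in% names(df)) df$quality else NULL
  rri_series(beat_times, rr = df$rr_s, quality = quality)
}

# Times (seconds) at which each interval is anchored for windowing and
# spectral analysis: the beat opening the interval.
rri_interval_times <- function(x) {
  x$beat_times[-length(x$beat_times)]
}
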
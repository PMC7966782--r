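#' Detect R-peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: zero-phase 5-15 Hz Butterworth band-pass,
#' differentiation, squaring and 150-ms moving-window integration, followed
#' by thresholding with a 200-ms refractory period. Each detection is refined
#' to the local maximum of the raw signal so peak times align with the QRS
#' apex.
#'
#' @param ecg an `ecg_record` (fields `samples`, `fs`) of at least 10 s.
#' @return numeric vector of beat times in seconds (possibly empty). A
#'   flatline or noise-dominated record yields an empty vector with a
#'   warning, not an error.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record") || is.list(ecg))
  x <- ecg$samples
  fs <- ecg$fs
  if (length(x) < 10 * fs) stop("record shorter than 10 s", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("flatline record: no R-peaks detected", call. = FALSE)
    return(numeric(0))
  }

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  der <- c(0, diff(bp))
  sq <- der^2
  w <- max(3L, round(0.15 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  thr <- 0.25 * stats::quantile(mwi, 0.98, names = FALSE)
  if (thr <= 0) {
    warning("no QRS energy above threshold", call. = FALSE)
    return(numeric(0))
  }
  above <- mwi > thr
  # candidate peaks: local maxima of the integrated signal above threshold
  n <- length(mwi)
  loc_max <- which(above &
                     mwi >= c(-Inf, mwi[-n]) &
                     mwi > c(mwi[-1], -Inf))
  if (length(loc_max) < 2L) {
    warning("fewer than two QRS candidates: record treated as noise",
            call. = FALSE)
    return(numeric(0))
  }

  refractory <- round(0.2 * fs)
  keep <- integer(0)
  last <- -Inf
  for (p in loc_max) {
    if (p - last >= refractory) {
      keep <- c(keep, p)
      last <- p
    } else if (mwi[p] > mwi[last]) {
      keep[length(keep)] <- p
      last <- p
    }
  }

  # refine to the raw-signal apex near each integrated-energy peak (the
  # integrator lags the QRS)
  half <- round(0.1 * fs)
  peaks <- vapply(keep, function(p) {
    lo <- max(1L, p - 2L * half)
    hi <- min(n, p + half)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  peaks <- sort(unique(peaks))
  # dedupe refined peaks closer than the refractory period
  if (length(peaks) > 1L) {
    ok <- c(TRUE, diff(peaks) >= refractory)
    while (!all(ok)) {
      drop <- which(!ok)[1]
      peaks <- peaks[-if (x[peaks[drop]] > x[peaks[drop - 1L]]) drop - 1L else drop]
      ok <- c(TRUE, diff(peaks) >= refractory)
    }
  }
  times <- (peaks - 1) / fs

  if (length(times) >= 2L) {
    d <- diff(times)
    med_rr <- stats::median(d)
    cv <- stats::sd(d) / mean(d)
    if (med_rr < 0.25 || med_rr > 3 || cv > 0.35) {
      warning("implausible beat sequence: record treated as noise",
              call. = FALSE)
      return(numeric(0))
    }
  }
  times
}

#' Edit an RR-interval series
#'
#' Identifies abnormal intervals — outside the absolute bounds
#' `[0.33, 1.5]` s or deviating more than 20% from the running median of the
#' 11 surrounding valid intervals — and corrects them by cubic-spline
#' interpolation over the neighbouring valid values, marking them
#' `"corrected"`. Abnormal runs longer than `max_correct_run`, and abnormal
#' intervals at the series edges, cannot be interpolated reliably and are
#' marked `"excluded"` instead. Editing is idempotent and is the identity on
#' artifact-free series.
#'
#' @param rri an [rri_series()] with at least 10 intervals.
#' @param abs_bounds absolute physiological bounds in seconds.
#' @param rel_tol maximum tolerated relative deviation from the local median.
#' @param max_correct_run longest consecutive abnormal run still corrected by
#'   interpolation.
#' @return an edited [rri_series()] with updated `rr` and `quality`.
#' @export
edit_rri <- function(rri, abs_bounds = c(0.33, 1.5), rel_tol = 0.2,
                     max_correct_run = 5L) {
  stopifnot(inherits(rri, "rri_series"))
  rr <- rri$rr
  n <- length(rr)
  if (n < 10L) stop("need at least 10 intervals to edit", call. = FALSE)
  quality <- rri$quality

  prior_excluded <- quality == "excluded"
  flag_abs <- !prior_excluded & (rr < abs_bounds[1] | rr > abs_bounds[2])

  # running median over the valid (in-bounds, not previously excluded)
  # subsequence; k = 11 surrounding intervals
  valid <- !prior_excluded & !flag_abs
  flag_rel <- logical(n)
  vi <- which(valid)
  if (length(vi) >= 3L) {
    k <- min(11L, length(vi) - (1 - length(vi) %% 2))  # odd, <= 11
    med <- stats::runmed(rr[vi], k, endrule = "median")
    # each interval (valid or not) is compared against the local median at
    # the nearest valid position
    nearest <- findInterval(seq_len(n), vi, all.inside = TRUE)
    ref <- med[pmax(1L, nearest)]
    flag_rel <- !prior_excluded & abs(rr - ref) > rel_tol * ref
  }

  flagged <- flag_abs | flag_rel
  if (mean(flagged | prior_excluded) > 0.5) {
    stop("more than half of the intervals are abnormal: series rejected as noise",
         call. = FALSE)
  }
  if (!any(flagged)) {
    return(rri)
  }

  # split flagged positions into correctable and excluded
  r <- rle(flagged | prior_excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  correct <- logical(n)
  exclude <- prior_excluded
  good <- which(!flagged & !prior_excluded)
  for (seg in which(r$values)) {
    idx <- starts[seg]:ends[seg]
    idx <- idx[flagged[idx]]
    if (!length(idx)) next
    run_len <- ends[seg] - starts[seg] + 1L
    at_edge <- starts[seg] == 1L || ends[seg] == n
    if (run_len > max_correct_run || at_edge || length(good) < 4L) {
      exclude[idx] <- TRUE
    } else {
      correct[idx] <- TRUE
    }
  }

  rr_new <- rr
  if (any(correct)) {
    sp <- stats::spline(x = good, y = rr[good], xout = which(correct),
                        method = "fmm")
    rr_new[correct] <- pmin(pmax(sp$y, abs_bounds[1]), abs_bounds[2])
  }
  quality[correct] <- "corrected"
  quality[exclude] <- "excluded"
  rri_series(rri$beat_times, rr = rr_new, quality = quality)
}

#' Convert a detected beat sequence to an RR-interval series
#'
#' @param beat_times beat times in seconds.
#' @return an [rri_series()].
#' @export
rri_from_beats <- function(beat_times) {
  rri_series(beat_times)
}

#' Write / read a single-channel EDF file
#'
#' Minimal European Data Format (EDF) support for one ECG channel: a standard
#' 256 + 256-byte header followed by 16-bit little-endian samples, with
#' linear physical scaling derived from the data range. The final data record
#' is zero-padded when the record duration does not divide the signal length.
#'
#' @param ecg an `ecg_record`.
#' @param path file path.
#' @param label channel label (default `"ECG"`).
#' @param record_duration_s data-record duration in seconds (default 1).
#' @return `write_edf()` returns `path` invisibly; `read_edf()` returns an
#'   `ecg_record`.
#' @export
write_edf <- function(ecg, path, label = "ECG", record_duration_s = 1) {
  stopifnot(inherits(ecg, "ecg_record"))
  x <- ecg$samples
  fs <- ecg$fs
  spr <- round(fs * record_duration_s)
  n_rec <- ceiling(length(x) / spr)
  pad <- n_rec * spr - length(x)
  if (pad > 0) x <- c(x, rep(0, pad))

  pmin_ <- min(x)
  pmax_ <- max(x)
  if (pmax_ == pmin_) {
    pmax_ <- pmin_ + 1
  }
  dmin <- -32768
  dmax <- 32767
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))

  fixed <- function(s, width) {
    s <- substr(sprintf("%-*s", width, s), 1, width)
    charToRaw(s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(fixed("0", 8), con)
  writeBin(fixed("synthetic", 80), con)
  writeBin(fixed("preictalHRV", 80), con)
  writeBin(fixed("01.01.00", 8), con)
  writeBin(fixed("00.00.00", 8), con)
  writeBin(fixed(as.character(256 + 256), 8), con)
  writeBin(fixed("", 44), con)
  writeBin(fixed(as.character(n_rec), 8), con)
  writeBin(fixed(format(record_duration_s), 8), con)
  writeBin(fixed("1", 4), con)
  writeBin(fixed(label, 16), con)
  writeBin(fixed("synthetic", 80), con)
  writeBin(fixed("mV", 8), con)
  writeBin(fixed(format(pmin_, digits = 7), 8), con)
  writeBin(fixed(format(pmax_, digits = 7), 8), con)
  writeBin(fixed(as.character(dmin), 8), con)
  writeBin(fixed(as.character(dmax), 8), con)
  writeBin(fixed("none", 80), con)
  writeBin(fixed(as.character(spr), 8), con)
  writeBin(fixed("", 32), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_edf
#' @param channel channel index to read (default 1).
#' @export
read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (channel > ns) stop("channel index out of range", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", spr[s], size = 2L, endian = "little",
                      signed = TRUE)
      if (s == channel) out <- c(out, vals)
    }
  }
  phys <- (out - dmin[channel]) / (dmax[channel] - dmin[channel]) *
    (pmax_[channel] - pmin_[channel]) + pmin_[channel]
  structure(
    list(samples = phys, fs = spr[channel] / rec_dur,
         label = labels[channel]),
    class = "ecg_record"
  )
}
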
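#' Configuration for the synthetic pre-seizure RRI generator
#'
#' The generator emulates a 240-min single-lead pre-seizure recording as an
#' RR-interval series with additive sinusoidal autonomic modulation in the LF
#' (default 0.1 Hz) and HF (default 0.25 Hz) bands, white beat-to-beat noise,
#' optional beat artifacts (ectopic splits and missed-beat merges), and an
#' optional planted preictal regime shift: a piecewise-constant change in mean
#' RR and/or LF modulation amplitude over a configurable interval before
#' seizure onset. Seizure onset is at the end of the generated span.
#'
#' The planted shift must lie entirely within the 120 min preceding onset,
#' matching the working hypothesis that only that span can carry
#' seizure-related cardiac changes; earlier data serve as an interictal
#' reference.
#'
#' @param total_span_min total generated span in minutes (>= 240).
#' @param mean_rr mean RR interval in seconds.
#' @param lf_freq,hf_freq modulation frequencies in Hz (low/high frequency
#'   autonomic bands).
#' @param lf_amp,hf_amp modulation amplitudes in seconds of RR.
#' @param white_noise_sd beat-to-beat Gaussian noise SD in seconds.
#' @param ectopic_rate,missed_rate per-beat artifact probabilities (each in
#'   `[0, 0.1]`).
#' @param shift_onset_min start of the planted shift, in minutes before
#'   seizure onset, or `NULL` for no shift.
#' @param shift_duration_min duration of the planted shift in minutes.
#' @param shift_delta_rr additive change in mean RR inside the shift
#'   (seconds).
#' @param shift_delta_lfhf multiplicative change in LF amplitude inside the
#'   shift.
#' @param rng_seed integer seed; all randomness in [generate_rri()] flows
#'   from it.
#' @return an object of class `synth_config`.
#' @seealso [generate_rri()], [simulate_cohort()]
#' @export
synth_config <- function(total_span_min = 240,
                         mean_rr = 0.85,
                         lf_freq = 0.1,
                         hf_freq = 0.25,
                         lf_amp = 0.02,
                         hf_amp = 0.015,
                         white_noise_sd = 0.01,
                         ectopic_rate = 0,
                         missed_rate = 0,
                         shift_onset_min = NULL,
                         shift_duration_min = 10,
                         shift_delta_rr = 0,
                         shift_delta_lfhf = 1,
                         rng_seed = 1L) {
  stop_if_not_scalar_number(total_span_min, "total_span_min")
  stop_if_not_scalar_number(mean_rr, "mean_rr")
  if (total_span_min < 240) {
    stop("total_span_min must be at least 240 minutes", call. = FALSE)
  }
  if (mean_rr <= 0) stop("mean_rr must be positive", call. = FALSE)
  for (r in c(ectopic_rate, missed_rate)) {
    if (!is.numeric(r) || r < 0 || r > 0.1) {
      stop("artifact rates must lie in [0, 0.1]", call. = FALSE)
    }
  }
  if (!is.null(shift_onset_min)) {
    stop_if_not_scalar_number(shift_onset_min, "shift_onset_min")
    stop_if_not_scalar_number(shift_duration_min, "shift_duration_min")
    if (shift_duration_min <= 0) {
      stop("shift_duration_min must be positive", call. = FALSE)
    }
    if (shift_onset_min > 120 || shift_onset_min - shift_duration_min < 0) {
      stop(
        "planted shift must lie entirely within the 120 min preceding ",
        "seizure onset (cardiac changes outside that span are treated as ",
        "interictal)",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      total_span_min = total_span_min, mean_rr = mean_rr,
      lf_freq = lf_freq, hf_freq = hf_freq,
      lf_amp = lf_amp, hf_amp = hf_amp,
      white_noise_sd = white_noise_sd,
      ectopic_rate = ectopic_rate, missed_rate = missed_rate,
      shift_onset_min = shift_onset_min,
      shift_duration_min = shift_duration_min,
      shift_delta_rr = shift_delta_rr,
      shift_delta_lfhf = shift_delta_lfhf,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic pre-seizure RR-interval series
#'
#' Beats are laid down sequentially from time 0; each RR interval is
#' `mean_rr + lf_amp * sin(2 * pi * lf_freq * t) + hf_amp * sin(2 * pi *
#' hf_freq * t) + noise`, evaluated at the time `t` of the beat opening the
#' interval, with the shift deltas applied to beats opening inside the planted
#' interval. Artifacts are injected after the clean series is built: an
#' ectopic event splits one RR into a short + long pair preserving total time;
#' a missed beat merges two adjacent RRs. Identical configurations (including
#' seed) give identical output.
#'
#' @param config a [synth_config()].
#' @return a list with components
#'   \describe{
#'     \item{rri}{an [rri_series()] spanning `total_span_min` minutes;}
#'     \item{truth}{a `ground_truth` list with `shift_start_s`/`shift_end_s`
#'       (absolute record time, `NA` when no shift is planted),
#'       `shift_onset_min`/`shift_duration_min`, `onset_s` (seizure onset =
#'       end of span) and per-beat artifact bookkeeping
#'       (`ectopic_intervals`, `missed_intervals`: indices into the clean
#'       series).}
#'   }
#' @examples
#' out <- generate_rri(synth_config(rng_seed = 7))
#' out$rri
#' @export
generate_rri <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  total_s <- config$total_span_min * 60
  onset_s <- total_s
  shift <- !is.null(config$shift_onset_min)
  shift_start <- if (shift) onset_s - config$shift_onset_min * 60 else NA_real_
  shift_end <- if (shift) shift_start + config$shift_duration_min * 60 else NA_real_

  with_local_seed(config$rng_seed, {
    # upper bound on beat count: shortest plausible RR
    min_rr <- max(
      config$mean_rr - abs(config$shift_delta_rr) -
        config$lf_amp - config$hf_amp - 6 * config$white_noise_sd,
      0.2
    )
    n_max <- ceiling(total_s / min_rr) + 10L
    noise <- if (config$white_noise_sd > 0) {
      stats::rnorm(n_max, sd = config$white_noise_sd)
    } else {
      numeric(n_max)
    }

    beat_times <- numeric(n_max + 1L)
    rr <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t < total_s - 1e-6 && i < n_max) {
      i <- i + 1L
      in_shift <- shift && t >= shift_start && t < shift_end
      mu <- config$mean_rr + if (in_shift) config$shift_delta_rr else 0
      lf_a <- config$lf_amp * if (in_shift) config$shift_delta_lfhf else 1
      val <- mu +
        lf_a * sin(2 * pi * config$lf_freq * t) +
        config$hf_amp * sin(2 * pi * config$hf_freq * t) +
        noise[i]
      if (val <= 0.2) val <- 0.2  # physiological floor, keeps beats ordered
      rr[i] <- val
      t <- t + val
      beat_times[i + 1L] <- t
    }
    beat_times <- beat_times[seq_len(i + 1L)]
    rr <- rr[seq_len(i)]

    # artifact injection on the clean series (beats change, cumulative time
    # does not, so window alignment is preserved)
    ect_idx <- integer(0)
    mis_idx <- integer(0)
    if (config$ectopic_rate > 0) {
      ect_idx <- which(stats::runif(length(rr)) < config$ectopic_rate)
    }
    if (config$missed_rate > 0) {
      cand <- which(stats::runif(length(rr) - 1L) < config$missed_rate)
      # never merge across an interval already used for an ectopic split
      cand <- setdiff(cand, c(ect_idx, ect_idx - 1L))
      # no overlapping merges
      keep <- cand[c(TRUE, diff(cand) > 1L)]
      mis_idx <- keep
    }
    split_frac <- stats::runif(length(ect_idx), 0.35, 0.45)

    if (length(ect_idx) || length(mis_idx)) {
      drop_beats <- mis_idx + 1L  # beat between the two merged intervals
      new_beats <- beat_times[ect_idx] + split_frac * rr[ect_idx]
      bt <- sort(c(setdiff_num(beat_times, beat_times[drop_beats]), new_beats))
      rri <- rri_series(bt)
    } else {
      rri <- rri_series(beat_times, rr = rr)
    }

    truth <- structure(
      list(
        shift_start_s = shift_start, shift_end_s = shift_end,
        shift_onset_min = if (shift) config$shift_onset_min else NA_real_,
        shift_duration_min = if (shift) config$shift_duration_min else NA_real_,
        onset_s = onset_s,
        ectopic_intervals = ect_idx,
        missed_intervals = mis_idx
      ),
      class = "ground_truth"
    )
    list(rri = rri, truth = truth)
  })
}

# numeric setdiff that tolerates exact duplicates (beat times are exact here)
setdiff_num <- function(x, drop) x[!(x %in% drop)]

#' Window indices overlapping the planted shift
#'
#' Maps a planted-shift ground truth onto a window grid: the indices of all
#' windows whose `[start, start + window_len)` span intersects the shift
#' interval. Empty when no shift was planted.
#'
#' @param truth a `ground_truth` from [generate_rri()].
#' @param grid a [build_window_grid()].
#' @return integer vector of window indices (possibly empty).
#' @export
ground_truth_windows <- function(truth, grid) {
  stopifnot(inherits(truth, "ground_truth"), inherits(grid, "window_grid"))
  if (is.na(truth$shift_start_s)) return(integer(0))
  starts <- window_starts(grid)
  ends <- starts + grid$window_len_s
  which(starts < truth$shift_end_s & ends > truth$shift_start_s)
}

#' Simulate a cohort of independent pre-seizure recordings
#'
#' Each seizure gets its own deterministic RNG substream derived from
#' `master_seed`, so enlarging the cohort never changes earlier seizures.
#'
#' @param n_seizures number of seizures (>= 1).
#' @param config_fn either a single [synth_config()] used as a template (its
#'   seed is replaced per seizure) or a function `(seizure_index, seed) ->
#'   synth_config`.
#' @param master_seed integer master seed.
#' @return a list of `n_seizures` elements, each the `list(rri, truth)` from
#'   [generate_rri()].
#' @export
simulate_cohort <- function(n_seizures, config_fn, master_seed = 1L) {
  stopifnot(n_seizures >= 1)
  lapply(seq_len(n_seizures), function(i) {
    seed_i <- derive_seed(master_seed, i)
    cfg <- if (is.function(config_fn)) {
      config_fn(i, seed_i)
    } else {
      stopifnot(inherits(config_fn, "synth_config"))
      cfg <- config_fn
      cfg$rng_seed <- seed_i
      cfg
    }
    generate_rri(cfg)
  })
}

#' Synthesize an ECG waveform from an RR-interval series
#'
#' Places a fixed QRS-like template (biphasic Gaussian-derivative, ~100 ms
#' support) at every beat time over a flat baseline — deliberately minimal
#' morphology, intended to exercise R-peak detection, not to model P/T waves.
#'
#' @param rri an [rri_series()].
#' @param fs sampling frequency in Hz (>= 128).
#' @return an object of class `ecg_record` with fields `samples` (mV), `fs`.
#' @export
generate_ecg <- function(rri, fs = 256) {
  stopifnot(inherits(rri, "rri_series"))
  if (fs < 128) stop("fs must be at least 128 Hz", call. = FALSE)
  half_w <- 0.05  # template half-width, seconds
  if (length(rri$rr) && min(rri$rr) <= 2 * half_w) {
    stop("beat interval shorter than the QRS template width", call. = FALSE)
  }
  if (!length(rri$beat_times)) {
    return(structure(list(samples = numeric(0), fs = fs), class = "ecg_record"))
  }
  # keep a short tail after the last beat so its QRS template fits and
  # detectors see no truncated complex at the record edge
  total_s <- max(rri$beat_times) + 0.3
  n <- floor(total_s * fs) + 1L
  samples <- numeric(n)
  half_n <- round(half_w * fs)
  tt <- (-half_n:half_n) / fs
  sigma <- 0.012
  template <- exp(-tt^2 / (2 * sigma^2)) - 0.35 * exp(-(tt - 0.025)^2 / (2 * (2 * sigma)^2))
  template <- template / max(template)
  for (bt in rri$beat_times) {
    centre <- round(bt * fs) + 1L
    lo <- centre - half_n
    hi <- centre + half_n
    sel <- lo:hi
    ok <- sel >= 1L & sel <= n
    samples[sel[ok]] <- samples[sel[ok]] + template[ok]
  }
  structure(list(samples = samples, fs = fs), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples at %g Hz (%.1f s)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth a `ground_truth` from [generate_rri()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("shift_start_s", "shift_end_s", "shift_onset_min",
              "shift_duration_min")) {
    if (is.null(x[[f]])) x[[f]] <- NA_real_
  }
  x$ectopic_intervals <- as.integer(x$ectopic_intervals)
  x$missed_intervals <- as.integer(x$missed_intervals)
  structure(x, class = "ground_truth")
}
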
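#' Canonical HRV feature set
#'
#' The 32 features computed per window, in fixed column order: nine linear
#' time-domain measures, seven frequency-domain band powers and ratios, and
#' sixteen nonlinear measures (Poincare dispersion, DFA exponents, entropies,
#' largest Lyapunov exponent, correlation dimension and seven RQA metrics).
#'
#' @return character vector of length 32.
#' @export
hrv_feature_names <- function() {
  c(
    "NN50", "pNN50", "SDNN", "RMSSD", "SDSD", "RRMean", "RRMin", "RRMax",
    "RRVar",
    "TotalPower", "VLF", "LF", "HF", "LFnorm", "HFnorm", "LF_HF",
    "SD1", "SD2", "SD1_SD2", "DFA_alpha1", "DFA_alpha2", "ApEn", "SampEn",
    "LLE", "CD",
    "REC", "L", "TT", "DET", "LAM", "ENT", "Lmax"
  )
}

# Minimum number of valid intervals required per feature group.
feature_min_n <- list(
  time = 2L, freq = 60L, poincare = 3L, dfa1 = 20L, dfa2 = 130L,
  entropy = 60L, rqa = 100L, lle = 200L, cd = 200L
)

#' HRV features of a single window
#'
#' Computes any subset of the 32 canonical features on one window's valid
#' intervals, respecting each feature group's minimum-length precondition
#' (features whose precondition fails come back `NA`).
#'
#' @param t beat times (seconds) anchoring each interval.
#' @param rr_s RR intervals in seconds.
#' @param features feature names, a subset of [hrv_feature_names()].
#' @param nl_params optional list overriding nonlinear defaults: `entropy_m`,
#'   `rqa_m`, `rqa_rec_target`, `lle_m`, `lle_theiler`, `cd_m`, `cd_theiler`.
#' @return named numeric vector over `features`.
#' @export
compute_window_features <- function(t, rr_s, features = hrv_feature_names(),
                                    nl_params = list()) {
  p <- utils::modifyList(
    list(entropy_m = 2L, rqa_m = 10L, rqa_rec_target = 0.1, lle_m = 10L,
         lle_theiler = 10L, cd_m = 10L, cd_theiler = 10L),
    nl_params
  )
  out <- stats::setNames(rep(NA_real_, length(features)), features)
  n <- length(rr_s)
  rr_ms <- rr_s * 1000

  want <- function(group) any(group %in% features)
  put <- function(vals) {
    sel <- intersect(names(vals), features)
    out[sel] <<- vals[sel]
  }

  td <- c("NN50", "pNN50", "SDNN", "RMSSD", "SDSD", "RRMean", "RRMin",
          "RRMax", "RRVar")
  if (want(td) && n >= feature_min_n$time) put(time_domain(rr_s))

  fd <- c("TotalPower", "VLF", "LF", "HF", "LFnorm", "HFnorm", "LF_HF")
  if (want(fd) && n >= feature_min_n$freq) put(frequency_domain(t, rr_s))

  pc <- c("SD1", "SD2", "SD1_SD2")
  if (want(pc) && n >= feature_min_n$poincare) put(poincare(rr_s))

  if (want(c("DFA_alpha1", "DFA_alpha2")) && n >= feature_min_n$dfa1) {
    a <- dfa(rr_ms)
    put(c(DFA_alpha1 = unname(a["alpha1"]), DFA_alpha2 = unname(a["alpha2"])))
  }

  if (want(c("ApEn", "SampEn")) && n >= feature_min_n$entropy) {
    e <- entropies(rr_ms, m = p$entropy_m, r_floor = 1)
    put(e)
  }

  rq <- c("REC", "L", "TT", "DET", "LAM", "ENT", "Lmax")
  if (want(rq) && n >= feature_min_n$rqa) {
    put(rqa(rr_ms, m = p$rqa_m, rec_target = p$rqa_rec_target))
  }

  if ("LLE" %in% features && n >= feature_min_n$lle) {
    if (stats::sd(rr_ms) > 0) {
      put(c(LLE = lle(rr_ms, m = p$lle_m, theiler = p$lle_theiler)))
    }
  }

  if ("CD" %in% features && n >= feature_min_n$cd) {
    put(c(CD = correlation_dimension(rr_ms, m = p$cd_m,
                                     theiler = p$cd_theiler)))
  }

  out
}

#' Extract the per-seizure feature matrix
#'
#' Slides the window grid over an edited RR-interval series and computes the
#' requested HRV features per window. A window is unusable — and masked for
#' all features — when it holds fewer than two valid intervals or when more
#' than `max_edit_frac` of its intervals were corrected or excluded by
#' editing; individual features are additionally missing when their own
#' length preconditions fail.
#'
#' @param rri an [rri_series()] covering the grid span (gaps allowed).
#' @param grid a [build_window_grid()].
#' @param features feature names to compute (default all 32).
#' @param max_edit_frac maximum tolerated fraction of corrected + excluded
#'   intervals per window (default 0.2).
#' @param nl_params nonlinear parameter overrides, see
#'   [compute_window_features()].
#' @return an object of class `feature_matrix`: list with `values` (windows x
#'   features), `mask` (`TRUE` where missing), `usable` (per-window logical),
#'   `grid`, `feature_names`.
#' @export
extract_features <- function(rri, grid, features = hrv_feature_names(),
                             max_edit_frac = 0.2, nl_params = list()) {
  stopifnot(inherits(rri, "rri_series"), inherits(grid, "window_grid"))
  features <- match.arg(features, hrv_feature_names(), several.ok = TRUE)
  tt <- rri_interval_times(rri)
  rr <- rri$rr
  valid <- rri$quality != "excluded"
  edited <- rri$quality != "valid"

  starts <- window_starts(grid)
  len <- grid$window_len_s
  lo <- findInterval(starts - 1e-9, tt) + 1L
  hi <- findInterval(starts + len - 1e-9, tt)

  W <- grid$n_windows
  values <- matrix(NA_real_, nrow = W, ncol = length(features),
                   dimnames = list(NULL, features))
  usable <- logical(W)
  for (w in seq_len(W)) {
    if (hi[w] < lo[w]) next
    sel <- lo[w]:hi[w]
    n_all <- length(sel)
    frac_edit <- sum(edited[sel]) / n_all
    ok <- sel[valid[sel]]
    if (length(ok) < 2L || frac_edit > max_edit_frac) next
    usable[w] <- TRUE
    values[w, ] <- compute_window_features(tt[ok], rr[ok], features,
                                           nl_params)
  }
  if (!any(usable)) {
    stop("no usable windows: the series does not cover the grid span",
         call. = FALSE)
  }
  structure(
    list(
      values = values,
      mask = is.na(values),
      usable = usable,
      grid = grid,
      feature_names = features
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d windows x %d features (%d usable windows, %.1f%% missing cells)\n",
    nrow(x$values), ncol(x$values), sum(x$usable), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' One row per window with a leading `time_before_onset_min` column (window
#' start, minutes before onset) and one column per feature; grid metadata
#' goes to a JSON sidecar `<path>.json`.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param path CSV path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns a `feature_matrix`.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(
    time_before_onset_min = window_start_before_onset(fm$grid),
    fm$values,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    span_min = fm$grid$span_min,
    window_len_s = fm$grid$window_len_s,
    step_s = fm$grid$step_s,
    usable = fm$usable,
    feature_names = fm$feature_names
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- build_window_grid(meta$span_min, meta$window_len_s, meta$step_s)
  values <- as.matrix(df[, meta$feature_names, drop = FALSE])
  structure(
    list(
      values = values,
      mask = is.na(values),
      usable = as.logical(meta$usable),
      grid = grid,
      feature_names = meta$feature_names
    ),
    class = "feature_matrix"
  )
}
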
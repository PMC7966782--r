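#' Study-wide selection parameters
#'
#' Bundles the thresholds of the solution-selection procedure: the Dunn's
#' index gate, the minimum smaller-cluster size, the analysed span, the span
#' searched for preictal candidates, the inter-seizure independence gap and
#' the seizure prediction horizon (SPH) — the minimum warning gap between an
#' alarm and seizure onset.
#'
#' @param sph_min SPH in minutes (default 10).
#' @param di_threshold minimum Dunn's index (default 0.15).
#' @param min_cluster_samples minimum smaller-cluster size (default 20).
#' @param analysis_span_min analysed pre-seizure span (default 240).
#' @param preictal_search_span_min span before onset in which a candidate may
#'   start (default 120).
#' @param independence_gap_min minimum separation between independent
#'   seizures (default 240).
#' @return an object of class `study_config`.
#' @export
study_config <- function(sph_min = 10, di_threshold = 0.15,
                         min_cluster_samples = 20L,
                         analysis_span_min = 240,
                         preictal_search_span_min = 120,
                         independence_gap_min = 240) {
  if (!(sph_min < preictal_search_span_min &&
        preictal_search_span_min <= analysis_span_min)) {
    stop("need sph < preictal_search_span <= analysis_span", call. = FALSE)
  }
  structure(
    list(
      sph_min = sph_min, di_threshold = di_threshold,
      min_cluster_samples = as.integer(min_cluster_samples),
      analysis_span_min = analysis_span_min,
      preictal_search_span_min = preictal_search_span_min,
      independence_gap_min = independence_gap_min
    ),
    class = "study_config"
  )
}

#' Classify the time continuity of a smaller cluster
#'
#' A cluster is continuous when its member windows are sequential over time.
#' In the default gap-tolerant mode, sequential is judged within the ordered
#' set of valid (non-missing) windows, so gaps caused solely by masked
#' windows do not break continuity — noise handling introduces missing
#' windows that would otherwise create pseudo-discontinuities. Strict mode
#' requires consecutive raw indices.
#'
#' @param windows integer member window indices (non-empty).
#' @param valid_windows integer indices of all valid windows (must contain
#'   `windows`).
#' @param strict require consecutive raw indices (default `FALSE`).
#' @return `"continuous"` or `"discontinuous"`.
#' @examples
#' classify_continuity(c(5, 6, 9), valid_windows = c(1:6, 9:12))
#' @export
classify_continuity <- function(windows, valid_windows = windows,
                                strict = FALSE) {
  windows <- sort(unique(as.integer(windows)))
  if (!length(windows)) stop("empty window set", call. = FALSE)
  if (strict) {
    return(if (all(diff(windows) == 1L)) "continuous" else "discontinuous")
  }
  valid_windows <- sort(unique(as.integer(valid_windows)))
  pos <- match(windows, valid_windows)
  if (anyNA(pos)) {
    stop("windows must be a subset of valid_windows", call. = FALSE)
  }
  if (length(pos) == 1L || all(diff(pos) == 1L)) "continuous" else "discontinuous"
}

#' Duration spanned by a cluster of overlapping windows
#'
#' With highly overlapping windows the informative duration of an n-window
#' cluster is the time between its first and last window starts:
#' `(n - 1) * step / 60` minutes, reported to two decimals. At the default
#' 5-s step, 20 windows span 1.58 min and 431 windows span 35.83 min.
#'
#' @param n_samples number of windows in the cluster (>= 1).
#' @param step_s window step in seconds (default 5).
#' @return duration in minutes, rounded to 2 decimals.
#' @examples
#' duration_minutes(20)
#' duration_minutes(431)
#' @export
duration_minutes <- function(n_samples, step_s = 5) {
  stopifnot(all(n_samples >= 1))
  round((n_samples - 1) * step_s / 60, 2)
}

#' Assemble a per-seizure preictal call from a clustering solution
#'
#' @param solution a `cluster_solution`.
#' @param grid the [build_window_grid()] the solution was computed on.
#' @param valid_windows indices of valid (non-masked) windows, used for
#'   continuity classification.
#' @param seizure_id identifier carried through to reports.
#' @param config a [study_config()].
#' @return an object of class `preictal_call` with the window span, the
#'   continuity class, the duration, the stratification bin and the SPH
#'   compatibility flag.
#' @export
preictal_call <- function(solution, grid, valid_windows = NULL,
                          seizure_id = NA, config = study_config()) {
  stopifnot(inherits(solution, "cluster_solution"),
            inherits(grid, "window_grid"))
  if (is.null(valid_windows)) valid_windows <- solution$window_index
  w <- solution$smaller_windows
  start_min <- window_start_before_onset(grid, min(w))
  end_min <- window_start_before_onset(grid, max(w))
  call <- structure(
    list(
      seizure_id = seizure_id,
      solution = solution,
      continuity = classify_continuity(w, valid_windows),
      duration_min = duration_minutes(solution$n_smaller, grid$step_s),
      start_min_before_onset = start_min,
      end_min_before_onset = end_min,
      bin = NA_character_,
      precedes_sph = NA
    ),
    class = "preictal_call"
  )
  call$bin <- stratify(call, config)
  call$precedes_sph <- sph_flag(call, config$sph_min)
  call
}

#' @export
print.preictal_call <- function(x, ...) {
  cat(sprintf(
    "<preictal_call> seizure %s: %s %s cluster of %d windows, %.2f min, starts %.2f min before onset (bin %s, precedes SPH: %s)\n",
    as.character(x$seizure_id), x$continuity, x$solution$method,
    x$solution$n_smaller, x$duration_min, x$start_min_before_onset,
    x$bin, x$precedes_sph
  ))
  invisible(x)
}

#' Select one clustering solution per seizure
#'
#' Continuous smaller clusters take precedence over discontinuous ones; among
#' the remaining candidates the solution whose smaller cluster has the most
#' windows wins (more windows, more statistical confidence in a preictal
#' state). Ties break by higher Dunn's index, then by lexicographic feature
#' combination, then by method name. The result is independent of input
#' order.
#'
#' @param accepted list of `cluster_solution` objects (possibly empty).
#' @param grid the [build_window_grid()] used.
#' @param valid_windows valid window indices for continuity classification.
#' @param seizure_id identifier for the resulting call.
#' @param config a [study_config()].
#' @return a `preictal_call`, or `NULL` when no solution was accepted.
#' @export
select_solution <- function(accepted, grid, valid_windows = NULL,
                            seizure_id = NA, config = study_config()) {
  if (!length(accepted)) return(NULL)
  vw <- valid_windows
  cont <- vapply(accepted, function(s) {
    classify_continuity(s$smaller_windows,
                        if (is.null(vw)) s$window_index else vw)
  }, character(1))
  pool <- if (any(cont == "continuous")) {
    accepted[cont == "continuous"]
  } else {
    accepted
  }
  key <- vapply(pool, function(s) {
    sprintf("%06d|%012.6f|%s|%s",
            s$n_smaller,
            min(s$dunn, 999999),
            paste(sprintf("%02d", 99 - s$combination), collapse = ""),
            s$method)
  }, character(1))
  # max n_smaller, then max DI, then lexicographically smallest combination
  # (encoded as 99 - index so that string max picks the smallest triple),
  # then method name
  best <- pool[[order(key, decreasing = TRUE, method = "radix")[1]]]
  preictal_call(best, grid, valid_windows = vw, seizure_id = seizure_id,
                config = config)
}

#' Stratify a preictal call into a 40-min pre-onset bin
#'
#' Bins are keyed on the start of the smaller cluster, measured in minutes
#' before seizure onset: `(80, 120] -> "120-80"`, `(40, 80] -> "80-40"`,
#' `[0, 40] -> "40-0"`. Clusters starting more than 120 min before onset
#' fall outside the preictal search span and are `"unstratified"`.
#'
#' @param call a `preictal_call` (or any list with
#'   `start_min_before_onset`).
#' @param config a [study_config()].
#' @return one of `"120-80"`, `"80-40"`, `"40-0"`, `"unstratified"`.
#' @export
stratify <- function(call, config = study_config()) {
  s <- call$start_min_before_onset
  if (s > config$preictal_search_span_min) return("unstratified")
  if (s > 80) "120-80" else if (s > 40) "80-40" else "40-0"
}

#' Does a call's interval entirely precede the seizure prediction horizon?
#'
#' `TRUE` when the smaller cluster ends at or before `sph_min` minutes before
#' onset, i.e. the candidate preictal interval leaves the full warning gap
#' intact.
#'
#' @param call a `preictal_call` (or any list with `end_min_before_onset`).
#' @param sph_min SPH in minutes (default 10).
#' @return logical.
#' @export
sph_flag <- function(call, sph_min = 10) {
  call$end_min_before_onset >= sph_min
}

#' Filter seizures for temporal independence
#'
#' A seizure is kept when at least `gap_min` minutes elapsed since the
#' immediately preceding seizure; the first seizure is kept when at least
#' `gap_min` minutes of recording precede it (configurable via
#' `require_lead_in`).
#'
#' @param onset_min seizure onset times in minutes from recording start,
#'   sorted ascending.
#' @param gap_min required separation (default 240).
#' @param recording_start_min recording start time (default 0).
#' @param require_lead_in require `gap_min` of recording before the first
#'   seizure (default `TRUE`).
#' @return logical keep-vector aligned with `onset_min`.
#' @examples
#' filter_independent_seizures(c(250, 350, 650))
#' @export
filter_independent_seizures <- function(onset_min, gap_min = 240,
                                        recording_start_min = 0,
                                        require_lead_in = TRUE) {
  if (is.unsorted(onset_min)) {
    stop("onset times must be sorted ascending", call. = FALSE)
  }
  n <- length(onset_min)
  if (!n) return(logical(0))
  keep <- logical(n)
  keep[1] <- if (require_lead_in) {
    onset_min[1] - recording_start_min >= gap_min
  } else {
    TRUE
  }
  if (n > 1) keep[-1] <- diff(onset_min) >= gap_min
  keep
}

#' Summarise preictal calls over a cohort
#'
#' Seizure-level accounting of the selection results: coverage (fraction of
#' analysed seizures with an accepted call), continuity proportions, bin
#' counts, and method / feature frequency tallies. When a seizure carries
#' calls in more than one bin, the per-patient tally counts the bin nearest
#' the seizure.
#'
#' @param calls list of `preictal_call` objects (may contain several calls
#'   per seizure) or `NULL` entries.
#' @param n_seizures total number of analysed seizures (default: number of
#'   distinct seizure ids among calls).
#' @param patient_ids optional named map seizure_id -> patient id for
#'   per-patient coverage.
#' @return list of data.frames: `overview`, `bins`, `methods`, `features`,
#'   and (when patient ids are given) `patients`.
#' @export
cohort_summary <- function(calls, n_seizures = NULL, patient_ids = NULL) {
  calls <- Filter(Negate(is.null), calls)
  if (!length(calls)) {
    return(list(
      overview = data.frame(
        n_seizures = if (is.null(n_seizures)) 0L else n_seizures,
        n_with_call = 0L, coverage_pct = NA_real_,
        pct_continuous = NA_real_, pct_precede_sph = NA_real_
      ),
      bins = data.frame(bin = character(0), n = integer(0)),
      methods = data.frame(method = character(0), n = integer(0)),
      features = data.frame(feature = character(0), n = integer(0))
    ))
  }
  sid <- vapply(calls, function(x) as.character(x$seizure_id), character(1))
  if (is.null(n_seizures)) n_seizures <- length(unique(sid))

  # one representative call per seizure: the bin nearest the seizure
  bin_rank <- c("40-0" = 1, "80-40" = 2, "120-80" = 3, "unstratified" = 4)
  per_seizure <- lapply(split(seq_along(calls), sid), function(ix) {
    ix[which.min(bin_rank[vapply(calls[ix], `[[`, "", "bin")])]
  })
  rep_calls <- calls[unlist(per_seizure)]

  cont <- vapply(rep_calls, `[[`, "", "continuity")
  sphf <- vapply(rep_calls, function(x) isTRUE(x$precedes_sph), logical(1))
  bins <- vapply(rep_calls, `[[`, "", "bin")
  methods <- vapply(calls, function(x) x$solution$method, character(1))
  feats <- unlist(lapply(calls, function(x) x$solution$feature_names))

  out <- list(
    overview = data.frame(
      n_seizures = n_seizures,
      n_with_call = length(rep_calls),
      coverage_pct = 100 * length(rep_calls) / n_seizures,
      pct_continuous = 100 * mean(cont == "continuous"),
      pct_precede_sph = 100 * mean(sphf)
    ),
    bins = as.data.frame(table(bin = bins), responseName = "n"),
    methods = as.data.frame(table(method = methods), responseName = "n"),
    features = as.data.frame(table(feature = feats), responseName = "n")
  )
  if (!is.null(patient_ids)) {
    pat <- patient_ids[vapply(rep_calls, function(x)
      as.character(x$seizure_id), character(1))]
    out$patients <- as.data.frame(table(patient = pat), responseName = "n")
  }
  out
}
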
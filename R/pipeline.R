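# End-to-end orchestration: synthetic cohort (or CSV RRI input) ->
# preprocessing -> features -> clustering scan -> selection -> report.
# Stages communicate through plain-text artifacts (CSV/JSON) so each can be
# re-run and tested in isolation.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "preictal-run",
    synthetic = list(
      n_seizures = 2L,
      total_span_min = 240,
      mean_rr = 0.85,
      lf_amp = 0.02,
      hf_amp = 0.015,
      white_noise_sd = 0.01,
      ectopic_rate = 0,
      missed_rate = 0,
      shift_onset_min = NULL,
      shift_duration_min = 10,
      shift_delta_rr = 0,
      shift_delta_lfhf = 1
    ),
    grid = list(span_min = 240, window_len_s = 300, step_s = 5),
    features = "all",
    methods = c("KM", "AH", "GMM", "DBSCAN_1", "DBSCAN_2", "DBSCAN_3",
                "DBSCAN_4"),
    edit = TRUE,
    selection = list(di_threshold = 0.15, min_cluster_samples = 20L,
                     sph_min = 10)
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration file (or accepts an equivalent list) and merges
#' it over the package defaults: a two-seizure synthetic cohort, the full
#' 240-min / 5-min / 5-s grid, all 32 features and all seven clustering
#' methods.
#'
#' @param config path to a YAML file, or a list.
#' @return a fully populated configuration list.
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("malformed config file", call. = FALSE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (identical(cfg$features, "all")) cfg$features <- hrv_feature_names()
  bad <- setdiff(cfg$features, hrv_feature_names())
  if (length(bad)) {
    stop("unknown feature(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

seizure_tag <- function(i) sprintf("seizure_%03d", i)

#' Pipeline stage: simulate a synthetic cohort
#'
#' Writes one RRI CSV and one ground-truth JSON per seizure under
#' `<out_dir>/rri/`. `shift_onset_min` may be a single value, `NULL` (no
#' shift), or a length-2 range from which each seizure draws uniformly (via
#' its own substream).
#'
#' @param config a configuration list or YAML path, see
#'   [load_pipeline_config()].
#' @return invisibly, the vector of RRI CSV paths.
#' @export
pipeline_simulate <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(file.path(cfg$out_dir, "rri"), recursive = TRUE,
             showWarnings = FALSE)
  sy <- cfg$synthetic
  make_cfg <- function(i, seed_i) {
    onset <- sy$shift_onset_min
    if (!is.null(onset) && length(onset) == 2L) {
      onset <- with_local_seed(seed_i + 1L,
                               stats::runif(1, onset[1], onset[2]))
    }
    synth_config(
      total_span_min = sy$total_span_min, mean_rr = sy$mean_rr,
      lf_amp = sy$lf_amp, hf_amp = sy$hf_amp,
      white_noise_sd = sy$white_noise_sd,
      ectopic_rate = sy$ectopic_rate, missed_rate = sy$missed_rate,
      shift_onset_min = onset,
      shift_duration_min = sy$shift_duration_min,
      shift_delta_rr = sy$shift_delta_rr,
      shift_delta_lfhf = sy$shift_delta_lfhf,
      rng_seed = seed_i
    )
  }
  cohort <- simulate_cohort(sy$n_seizures, make_cfg, master_seed = cfg$seed)
  paths <- character(0)
  for (i in seq_along(cohort)) {
    tag <- seizure_tag(i)
    p <- file.path(cfg$out_dir, "rri", paste0(tag, ".csv"))
    write_rri_csv(cohort[[i]]$rri, p)
    write_ground_truth(cohort[[i]]$truth,
                       file.path(cfg$out_dir, "rri", paste0(tag, "_truth.json")))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Pipeline stage: extract feature matrices
#'
#' Reads every RRI CSV under `<out_dir>/rri/`, optionally edits it, lays the
#' window grid and writes one feature CSV (+ JSON grid sidecar) per seizure
#' under `<out_dir>/features/`.
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the vector of feature CSV paths.
#' @export
pipeline_features <- function(config) {
  cfg <- load_pipeline_config(config)
  rri_dir <- file.path(cfg$out_dir, "rri")
  files <- sort(list.files(rri_dir, pattern = "^seizure_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) {
    stop("no RRI artifacts found under ", rri_dir,
         "; run the simulate stage (or place seizure_*.csv there) first",
         call. = FALSE)
  }
  grid <- build_window_grid(cfg$grid$span_min, cfg$grid$window_len_s,
                            cfg$grid$step_s)
  dir.create(file.path(cfg$out_dir, "features"), showWarnings = FALSE)
  out <- character(0)
  for (f in files) {
    tag <- sub("\\.csv$", "", basename(f))
    res <- tryCatch({
      rri <- read_rri_csv(f)
      if (isTRUE(cfg$edit)) rri <- edit_rri(rri)
      fm <- extract_features(rri, grid, features = cfg$features)
      p <- file.path(cfg$out_dir, "features", paste0(tag, ".csv"))
      write_feature_csv(fm, p)
      p
    }, error = function(e) {
      message(sprintf("[%s] skipped in feature stage: %s", tag,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) out <- c(out, res)
  }
  if (!length(out)) stop("no seizure survived the feature stage", call. = FALSE)
  invisible(out)
}

solution_to_record <- function(s) {
  list(
    combination = s$combination,
    feature_names = s$feature_names,
    method = s$method,
    window_index = s$window_index,
    smaller_windows = s$smaller_windows,
    n_smaller = s$n_smaller,
    dunn = s$dunn
  )
}

record_to_solution <- function(rec) {
  structure(
    list(
      combination = as.integer(rec$combination),
      feature_names = as.character(rec$feature_names),
      method = rec$method,
      labels = NULL,
      window_index = as.integer(rec$window_index),
      smaller_windows = as.integer(rec$smaller_windows),
      n_smaller = as.integer(rec$n_smaller),
      dunn = as.numeric(rec$dunn)
    ),
    class = "cluster_solution"
  )
}

#' Pipeline stage: exhaustive clustering scan
#'
#' Runs the three-feature clustering search on every feature matrix under
#' `<out_dir>/features/` and writes, per seizure, the accepted solutions as a
#' JSON file plus a cohort-wide audit log `scan_log.csv` (seizure, feature
#' triple, method, smaller-cluster size, Dunn's index, window span).
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, the audit-log data.frame.
#' @export
pipeline_scan <- function(config) {
  cfg <- load_pipeline_config(config)
  fdir <- file.path(cfg$out_dir, "features")
  files <- sort(list.files(fdir, pattern = "^seizure_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) {
    stop("no feature artifacts found under ", fdir,
         "; run the features stage first", call. = FALSE)
  }
  dir.create(file.path(cfg$out_dir, "scan"), showWarnings = FALSE)
  log_rows <- list()
  for (f in files) {
    tag <- sub("\\.csv$", "", basename(f))
    fm <- read_feature_csv(f)
    res <- scan_seizure(
      fm,
      methods = cfg$methods,
      seed = derive_seed(cfg$seed, which(files == f)),
      min_samples = cfg$selection$min_cluster_samples,
      di_threshold = cfg$selection$di_threshold
    )
    jsonlite::write_json(
      list(
        seizure = tag,
        n_combinations = res$n_combinations,
        n_candidates = res$n_candidates,
        usable_windows = which(fm$usable),
        accepted = lapply(res$accepted, solution_to_record)
      ),
      file.path(cfg$out_dir, "scan", paste0(tag, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    for (s in res$accepted) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        seizure = tag,
        combination = paste(s$feature_names, collapse = "+"),
        method = s$method,
        n_smaller = s$n_smaller,
        dunn = s$dunn,
        first_window = min(s$smaller_windows),
        last_window = max(s$smaller_windows)
      )
    }
  }
  log_df <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(seizure = character(0), combination = character(0),
               method = character(0), n_smaller = integer(0),
               dunn = numeric(0), first_window = integer(0),
               last_window = integer(0))
  }
  utils::write.csv(log_df, file.path(cfg$out_dir, "scan", "scan_log.csv"),
                   row.names = FALSE)
  invisible(log_df)
}

#' Pipeline stage: per-seizure solution selection
#'
#' Applies the continuity-then-duration selection to each seizure's accepted
#' solutions and writes the resulting preictal calls as JSON lines
#' (`<out_dir>/calls.jsonl`).
#'
#' @inheritParams pipeline_simulate
#' @return invisibly, a list of `preictal_call` objects (with `NULL` for
#'   seizures without an accepted solution).
#' @export
pipeline_select <- function(config) {
  cfg <- load_pipeline_config(config)
  sdir <- file.path(cfg$out_dir, "scan")
  files <- sort(list.files(sdir, pattern = "^seizure_[0-9]+\\.json$",
                           full.names = TRUE))
  if (!length(files)) {
    stop("no scan artifacts found under ", sdir,
         "; run the scan stage first", call. = FALSE)
  }
  grid <- build_window_grid(cfg$grid$span_min, cfg$grid$window_len_s,
                            cfg$grid$step_s)
  sc <- study_config(
    sph_min = cfg$selection$sph_min,
    di_threshold = cfg$selection$di_threshold,
    min_cluster_samples = cfg$selection$min_cluster_samples,
    analysis_span_min = cfg$grid$span_min
  )
  calls <- list()
  con <- file(file.path(cfg$out_dir, "calls.jsonl"), "w")
  on.exit(close(con))
  for (f in files) {
    rec <- jsonlite::read_json(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    sols <- lapply(rec$accepted, record_to_solution)
    call <- select_solution(
      sols, grid, valid_windows = as.integer(rec$usable_windows),
      seizure_id = rec$seizure, config = sc
    )
    calls[[rec$seizure]] <- call
    if (!is.null(call)) {
      writeLines(jsonlite::toJSON(list(
        seizure_id = call$seizure_id,
        method = call$solution$method,
        features = call$solution$feature_names,
        n_smaller = call$solution$n_smaller,
        dunn = call$solution$dunn,
        continuity = call$continuity,
        duration_min = call$duration_min,
        start_min_before_onset = call$start_min_before_onset,
        end_min_before_onset = call$end_min_before_onset,
        bin = call$bin,
        precedes_sph = call$precedes_sph,
        smaller_windows = call$solution$smaller_windows
      ), auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(calls)
}

#' Pipeline stage: cohort report
#'
#' Summarises the calls of [pipeline_select()] into `report_overview.csv`,
#' `report_bins.csv`, `report_methods.csv` and `report_features.csv` under
#' `out_dir`, plus a short human-readable `report.txt`.
#'
#' @inheritParams pipeline_simulate
#' @param calls optional list of calls (default: re-run the select stage).
#' @return invisibly, the [cohort_summary()] list.
#' @export
pipeline_report <- function(config, calls = NULL) {
  cfg <- load_pipeline_config(config)
  if (is.null(calls)) calls <- pipeline_select(cfg)
  n_seizures <- length(calls)
  rep <- cohort_summary(unname(calls),
                        n_seizures = max(n_seizures, 1L))
  for (nm in c("overview", "bins", "methods", "features")) {
    utils::write.csv(rep[[nm]],
                     file.path(cfg$out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  txt <- c(
    sprintf("Seizures analysed: %d", rep$overview$n_seizures),
    sprintf("Seizures with an accepted preictal call: %d (%.0f%%)",
            rep$overview$n_with_call,
            ifelse(is.na(rep$overview$coverage_pct), 0,
                   rep$overview$coverage_pct)),
    if (nrow(rep$bins)) {
      paste0("Bins: ",
             paste(sprintf("%s: %d", rep$bins$bin, rep$bins$n),
                   collapse = ", "))
    } else {
      "Bins: none"
    }
  )
  writeLines(txt, file.path(cfg$out_dir, "report.txt"))
  invisible(rep)
}

#' Run the full pipeline
#'
#' Simulate (when a synthetic cohort is configured and no RRI artifacts
#' exist yet), extract features, scan, select, report. Individual seizure
#' failures are logged and skipped; the run fails only when no seizure
#' survives a stage. A run manifest (`manifest.json`) captures the seed, the
#' configuration, the package version and per-stage timing so that equal
#' manifests imply identical artifacts.
#'
#' @param config configuration list or YAML path, see
#'   [load_pipeline_config()].
#' @return invisibly, the cohort report list.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timing <- c()
  step <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  rri_dir <- file.path(cfg$out_dir, "rri")
  if (!length(list.files(rri_dir, pattern = "\\.csv$"))) {
    step("simulate", function() pipeline_simulate(cfg))
  }
  step("features", function() pipeline_features(cfg))
  step("scan", function() pipeline_scan(cfg))
  calls <- step("select", function() pipeline_select(cfg))
  rep <- step("report", function() pipeline_report(cfg, calls = calls))

  cfg_tmp <- tempfile()
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], cfg_tmp)
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("preictalHRV")),
    timing_s = as.list(timing)
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
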
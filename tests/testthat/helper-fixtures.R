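# Small fixture builders shared across test files.

# RRI series from explicit interval values (seconds), beats laid end to end
make_rri <- function(rr, quality = NULL) {
  rri_series(c(0, cumsum(rr)), rr = rr, quality = quality)
}

# seeded RR window: mean 0.85 s with Gaussian jitter
random_window <- function(n, seed, sd = 0.05) {
  set.seed(seed)
  pmax(0.4, stats::rnorm(n, 0.85, sd))
}

# two well-separated 3-D Gaussian blobs; returns list(X, truth_small)
two_blobs <- function(n_big = 100, n_small = 30, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_big * 3), ncol = 3),
    matrix(stats::rnorm(n_small * 3), ncol = 3) + sep
  )
  list(X = X, small = n_big + seq_len(n_small))
}

# recovery-experiment driver shared by the end-to-end acceptance test: one
# 240-min synthetic seizure -> features on a 60-s/20-s grid (8 continuous
# time-domain/Poincare features) -> KM + DBSCAN_2 + GMM scan -> selection
recovery_grid <- function() build_window_grid(240, 60, 20)

recovery_features <- function() {
  c("SDNN", "RMSSD", "SDSD", "RRMean", "RRMin", "RRMax", "SD1", "SD2")
}

run_recovery_seizure <- function(seed, planted) {
  onset <- if (planted) {
    preictalHRV:::with_local_seed(seed + 1L, stats::runif(1, 20, 60))
  } else {
    NULL
  }
  cfg <- synth_config(
    shift_onset_min = onset, shift_duration_min = 10,
    shift_delta_rr = if (planted) -0.08 else 0,
    rng_seed = seed
  )
  out <- generate_rri(cfg)
  grid <- recovery_grid()
  fm <- extract_features(out$rri, grid, features = recovery_features())
  res <- scan_seizure(fm, methods = c("KM", "DBSCAN_2", "GMM"), seed = seed)
  call <- select_solution(res$accepted, grid,
                          valid_windows = which(fm$usable),
                          seizure_id = seed)
  list(call = call, truth = out$truth, grid = grid)
}
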
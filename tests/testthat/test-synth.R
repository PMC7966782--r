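test_that("noise-free constant-rate config yields the exact beat lattice", {
  cfg <- synth_config(mean_rr = 0.8, lf_amp = 0, hf_amp = 0,
                      white_noise_sd = 0, rng_seed = 1)
  out <- generate_rri(cfg)
  expect_equal(length(out$rri$rr), 18000L)
  expect_true(all(out$rri$rr == 0.8))
  expect_equal(max(out$rri$beat_times), 14400)
})

test_that("LF-only modulation concentrates spectral power in the LF band", {
  cfg <- synth_config(mean_rr = 0.85, lf_amp = 0.05, hf_amp = 0,
                      white_noise_sd = 0, rng_seed = 1)
  out <- generate_rri(cfg)
  t <- out$rri$beat_times[-length(out$rri$beat_times)]
  # periodogram of a 20-min stretch is ample to resolve the band
  sel <- t < 1200
  psd <- lomb_psd(t[sel], out$rri$rr[sel], fmin = 0.003, fmax = 0.4)
  lf <- sum(psd$power[psd$freq >= 0.04 & psd$freq < 0.15])
  expect_gt(lf / sum(psd$power), 0.99)
})

test_that("planted shift changes the mean RR by exactly the configured delta", {
  cfg <- synth_config(mean_rr = 0.85, lf_amp = 0, hf_amp = 0,
                      white_noise_sd = 0, shift_onset_min = 30,
                      shift_duration_min = 10, shift_delta_rr = -0.1,
                      rng_seed = 1)
  out <- generate_rri(cfg)
  t <- out$rri$beat_times[-length(out$rri$beat_times)]
  inside <- t >= out$truth$shift_start_s & t < out$truth$shift_end_s
  expect_lt(abs(mean(out$rri$rr[inside]) - 0.75), 1e-9)
})

test_that("shift intervals outside the 120-min pre-onset span are rejected", {
  expect_error(synth_config(shift_onset_min = 130, shift_duration_min = 10),
               "120 min")
  expect_error(synth_config(shift_onset_min = 5, shift_duration_min = 10),
               "120 min")
  expect_s3_class(synth_config(shift_onset_min = 120, shift_duration_min = 10),
                  "synth_config")
})

test_that("generation is deterministic and elapsed time equals the RR sum", {
  cfg <- synth_config(ectopic_rate = 0.01, missed_rate = 0.01, rng_seed = 99)
  a <- generate_rri(cfg)
  b <- generate_rri(cfg)
  expect_identical(a, b)
  elapsed <- max(a$rri$beat_times) - min(a$rri$beat_times)
  expect_lt(abs(elapsed - sum(a$rri$rr)), 1e-6)
})

test_that("artifact injection preserves cumulative time", {
  clean <- generate_rri(synth_config(rng_seed = 7))
  dirty <- generate_rri(synth_config(ectopic_rate = 0.02, missed_rate = 0.02,
                                     rng_seed = 7))
  expect_lt(abs(sum(dirty$rri$rr) - sum(clean$rri$rr)), 1e-9)
  expect_gt(length(dirty$truth$ectopic_intervals), 0)
  expect_gt(length(dirty$truth$missed_intervals), 0)
})

test_that("cohort simulation is reproducible and prefix-stable", {
  cfg <- synth_config(rng_seed = 1)
  a <- simulate_cohort(2, cfg, master_seed = 5)
  b <- simulate_cohort(2, cfg, master_seed = 5)
  expect_identical(a, b)
  c3 <- simulate_cohort(3, cfg, master_seed = 5)
  expect_identical(a[[1]], c3[[1]])
  expect_identical(a[[2]], c3[[2]])
})

test_that("shift-free ground truth maps to an empty window set", {
  out <- generate_rri(synth_config(rng_seed = 3))
  grid <- build_window_grid(240, 300, 60)
  expect_identical(ground_truth_windows(out$truth, grid), integer(0))
})

test_that("planted-shift windows are consistent with the grid mapping", {
  cfg <- synth_config(shift_onset_min = 60, shift_duration_min = 10,
                      shift_delta_rr = -0.05, rng_seed = 3)
  out <- generate_rri(cfg)
  grid <- build_window_grid(240, 300, 60)
  w <- ground_truth_windows(out$truth, grid)
  starts <- (w - 1) * grid$step_s
  ends <- starts + grid$window_len_s
  expect_true(all(starts < out$truth$shift_end_s &
                    ends > out$truth$shift_start_s))
  # neighbours just outside do not overlap
  expect_false((min(w) - 2) * grid$step_s + grid$window_len_s >
                 out$truth$shift_start_s)
})

test_that("RRI CSV and ground-truth JSON round-trip", {
  out <- generate_rri(synth_config(shift_onset_min = 40,
                                   shift_duration_min = 10,
                                   shift_delta_rr = -0.1, rng_seed = 11))
  p <- withr::local_tempfile(fileext = ".csv")
  write_rri_csv(out$rri, p)
  back <- read_rri_csv(p)
  expect_equal(back$rr, out$rri$rr, tolerance = 1e-12)
  expect_equal(back$quality, out$rri$quality)
  pj <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(out$truth, pj)
  tr <- read_ground_truth(pj)
  expect_equal(tr$shift_start_s, out$truth$shift_start_s)
  expect_equal(tr$shift_end_s, out$truth$shift_end_s)
})

test_that("synthetic ECG places template peaks on the beat lattice", {
  bt <- seq(0, 60, by = 0.8)
  ecg <- generate_ecg(rri_series(bt), fs = 256)
  pk <- detect_r_peaks(ecg)
  gaps <- round(diff(pk) * 256)
  expect_true(all(gaps %in% c(204, 205)))  # 0.8 * 256 = 204.8
})

test_that("empty RRI gives a flat zero record and short beats error", {
  flat <- generate_ecg(rri_series(numeric(0)), fs = 256)
  expect_identical(flat$samples, numeric(0))
  expect_error(generate_ecg(make_rri(rep(0.09, 20)), fs = 256), "template")
})

test_that("ECG round-trip recovers every beat within one sample", {
  out <- generate_rri(synth_config(rng_seed = 4))
  short <- rri_series(out$rri$beat_times[out$rri$beat_times < 240])
  ecg <- generate_ecg(short, fs = 256)
  pk <- detect_r_peaks(ecg)
  expect_equal(length(pk), length(short$beat_times))
  err <- vapply(short$beat_times, function(b) min(abs(pk - b)), numeric(1))
  expect_lt(max(err), 1 / 256 + 1e-9)
})
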
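test_that("flatline and noise-only records yield no peaks, with a warning", {
  flat <- structure(list(samples = rep(0, 256 * 30), fs = 256),
                    class = "ecg_record")
  expect_warning(pk <- detect_r_peaks(flat), "flatline")
  expect_length(pk, 0)
  set.seed(21)
  noise <- structure(list(samples = rnorm(256 * 60), fs = 256),
                     class = "ecg_record")
  expect_warning(pkn <- detect_r_peaks(noise), "noise")
  expect_length(pkn, 0)
})

test_that("constant 75-bpm synthetic ECG is detected beat for beat", {
  bt <- seq(0, by = 0.8, length.out = 300)  # 4 min at 75 bpm
  ecg <- generate_ecg(rri_series(bt), fs = 256)
  pk <- detect_r_peaks(ecg)
  expect_true(abs(length(pk) - 300) <= 1)
  err <- vapply(bt, function(b) min(abs(pk - b)), numeric(1))
  expect_lt(max(err), 1 / 256 + 1e-9)
})

test_that("detection stays above 99% sensitivity and PPV at 10 dB SNR", {
  out <- generate_rri(synth_config(rng_seed = 8))
  short <- rri_series(out$rri$beat_times[out$rri$beat_times < 300])
  ecg <- generate_ecg(short, fs = 256)
  set.seed(80)
  snr_sd <- sqrt(mean(ecg$samples^2) / 10)
  ecg$samples <- ecg$samples + rnorm(length(ecg$samples), sd = snr_sd)
  pk <- detect_r_peaks(ecg)
  bt <- short$beat_times
  tol <- 0.05
  sens <- mean(vapply(bt, function(b) any(abs(pk - b) <= tol), logical(1)))
  ppv <- mean(vapply(pk, function(p) any(abs(bt - p) <= tol), logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(ppv, 0.99)
})

test_that("editing is the identity on clean series", {
  x <- make_rri(rep(0.8, 200))
  y <- edit_rri(x)
  expect_identical(y$rr, x$rr)
  expect_true(all(y$quality == "valid"))
})

test_that("an ectopic short+long pair is corrected back to the local rhythm", {
  rr <- rep(0.8, 100)
  rr[50] <- 0.4
  rr[51] <- 1.2
  y <- edit_rri(make_rri(rr))
  expect_setequal(which(y$quality == "corrected"), c(50L, 51L))
  expect_true(all(abs(y$rr[50:51] - 0.8) < 0.05))
  expect_true(all(y$rr[-(50:51)] == 0.8))
})

test_that("intervals outside the absolute bounds are flagged", {
  rr <- rep(0.8, 60)
  rr[30] <- 2.5
  y <- edit_rri(make_rri(rr))
  expect_false(y$quality[30] == "valid")
  rr2 <- rep(0.8, 60)
  rr2[30] <- 0.25
  y2 <- edit_rri(make_rri(rr2))
  expect_false(y2$quality[30] == "valid")
})

test_that("editing is idempotent", {
  set.seed(31)
  rr <- rnorm(300, 0.8, 0.02)
  rr[c(40, 41, 120, 200)] <- c(0.4, 1.3, 2.0, 0.3)
  once <- edit_rri(make_rri(rr))
  twice <- edit_rri(once)
  expect_identical(twice$rr, once$rr)
  expect_identical(twice$quality, once$quality)
})

test_that("mostly-abnormal series are rejected as noise", {
  set.seed(12)
  rr <- runif(100, 0.1, 3)
  expect_error(edit_rri(make_rri(rr)), "noise")
})

test_that("long abnormal runs are excluded rather than interpolated", {
  rr <- rep(0.8, 120)
  rr[40:52] <- 2.0  # 13-interval dropout, beyond the correctable run length
  y <- edit_rri(make_rri(rr))
  expect_true(all(y$quality[40:52] == "excluded"))
})

test_that("EDF round-trips a synthetic ECG channel", {
  out <- generate_rri(synth_config(rng_seed = 2))
  short <- rri_series(out$rri$beat_times[out$rri$beat_times < 32])
  ecg <- generate_ecg(short, fs = 128)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(ecg, p, record_duration_s = 1)
  back <- read_edf(p)
  expect_equal(back$fs, 128)
  n <- length(ecg$samples)
  # 16-bit quantisation: agreement to ~1e-4 of the dynamic range
  expect_lt(max(abs(back$samples[seq_len(n)] - ecg$samples)),
            diff(range(ecg$samples)) * 1e-4)
})
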
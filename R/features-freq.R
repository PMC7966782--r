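#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic Lomb normalised periodogram with the per-frequency time offset
#' `tau`, evaluated on a regular frequency grid and rescaled so that the
#' periodogram integrates (trapezoidal rule) to the sample variance of `x`.
#' Working directly on the (beat time, RR) pairs avoids the interpolation
#' bias of resampling the tachogram.
#'
#' @param t sample times in seconds.
#' @param x sample values.
#' @param fmin,fmax frequency range in Hz.
#' @param oversample frequency oversampling factor relative to `1 / span`.
#' @return data.frame with columns `freq` (Hz) and `power` (variance density,
#'   x-units^2 per Hz).
#' @export
lomb_psd <- function(t, x, fmin = 0.003, fmax = 0.4, oversample = 4) {
  stopifnot(length(t) == length(x), length(t) >= 4)
  keep <- is.finite(t) & is.finite(x)
  t <- t[keep]
  x <- x[keep]
  span <- diff(range(t))
  if (span <= 0) stop("degenerate time span", call. = FALSE)
  df <- 1 / (span * oversample)
  freq <- seq(max(fmin, df / 2), fmax, by = df)
  xc <- x - mean(x)
  varx <- stats::var(x)
  if (varx == 0) {
    return(data.frame(freq = freq, power = rep(0, length(freq))))
  }
  omega <- 2 * pi * freq
  # tau per frequency: tan(2 w tau) = sum sin(2 w t) / sum cos(2 w t)
  s2 <- vapply(omega, function(w) sum(sin(2 * w * t)), numeric(1))
  c2 <- vapply(omega, function(w) sum(cos(2 * w * t)), numeric(1))
  tau <- atan2(s2, c2) / (2 * omega)
  p <- vapply(seq_along(omega), function(j) {
    w <- omega[j]
    arg <- w * (t - tau[j])
    ca <- cos(arg)
    sa <- sin(arg)
    0.5 * ((sum(xc * ca))^2 / sum(ca^2) + (sum(xc * sa))^2 / sum(sa^2))
  }, numeric(1))
  # rescale so the grid integral equals the series variance
  integral <- sum((p[-1] + p[-length(p)]) / 2) * df
  power <- if (integral > 0) p * varx / integral else p
  data.frame(freq = freq, power = power)
}

# trapezoidal band integral of a periodogram
band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  f <- psd$freq[sel]
  p <- psd$power[sel]
  if (length(f) < 2L) return(0)
  sum((p[-1] + p[-length(p)]) / 2 * diff(f))
}

#' Frequency-domain HRV features of one window
#'
#' Band powers of the RR tachogram from the Lomb-Scargle periodogram over the
#' standard short-term bands: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF
#' 0.15-0.40 Hz. `TotalPower = VLF + LF + HF`; normalised powers
#' `LFnorm = 100 * LF / (LF + HF)` (and symmetrically `HFnorm`);
#' `LF_HF = LF / HF`, reported missing rather than infinite when `HF = 0`.
#' Powers are in ms^2.
#'
#' @param t beat times in seconds anchoring each interval.
#' @param rr_s RR intervals in seconds (>= 60 values).
#' @return named numeric vector `TotalPower`, `VLF`, `LF`, `HF`, `LFnorm`,
#'   `HFnorm`, `LF_HF`.
#' @export
frequency_domain <- function(t, rr_s) {
  out <- stats::setNames(
    rep(NA_real_, 7),
    c("TotalPower", "VLF", "LF", "HF", "LFnorm", "HFnorm", "LF_HF")
  )
  keep <- is.finite(t) & is.finite(rr_s)
  t <- t[keep]
  rr <- rr_s[keep] * 1000  # ms
  if (length(rr) < 60L) return(out)
  if (stats::var(rr) == 0) {
    out[c("TotalPower", "VLF", "LF", "HF")] <- 0
    return(out)
  }
  psd <- lomb_psd(t, rr, fmin = 0.003, fmax = 0.4)
  vlf <- band_power(psd, 0.003, 0.04)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  out["VLF"] <- vlf
  out["LF"] <- lf
  out["HF"] <- hf
  out["TotalPower"] <- vlf + lf + hf
  if (lf + hf > 0) {
    out["LFnorm"] <- 100 * lf / (lf + hf)
    out["HFnorm"] <- 100 * hf / (lf + hf)
  }
  out["LF_HF"] <- if (hf > 0) lf / hf else NA_real_
  out
}
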
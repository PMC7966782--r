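#' Time-domain HRV features of one window
#'
#' Computes the nine linear time-domain measures on the valid RR intervals of
#' a window. Units are milliseconds (ms^2 for `RRVar`). Sample (n - 1)
#' standard deviations are used throughout.
#'
#' @param rr_s numeric vector of RR intervals in seconds (>= 2 values for the
#'   dispersion measures).
#' @return named numeric vector with elements `NN50`, `pNN50`, `SDNN`,
#'   `RMSSD`, `SDSD`, `RRMean`, `RRMin`, `RRMax`, `RRVar` (all `NA` when
#'   fewer than two intervals are supplied).
#' @examples
#' time_domain(rep(0.8, 10))
#' @export
time_domain <- function(rr_s) {
  out <- stats::setNames(
    rep(NA_real_, 9),
    c("NN50", "pNN50", "SDNN", "RMSSD", "SDSD", "RRMean", "RRMin", "RRMax",
      "RRVar")
  )
  rr_s <- rr_s[is.finite(rr_s)]
  n <- length(rr_s)
  if (n < 2L) return(out)
  rr <- rr_s * 1000  # ms
  d <- diff(rr)
  out["NN50"] <- sum(abs(d) > 50)
  out["pNN50"] <- 100 * out["NN50"] / (n - 1)
  out["SDNN"] <- stats::sd(rr)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["SDSD"] <- stats::sd(d)
  out["RRMean"] <- mean(rr)
  out["RRMin"] <- min(rr)
  out["RRMax"] <- max(rr)
  out["RRVar"] <- stats::var(rr)
  out
}

#' Poincare-plot dispersion of one window
#'
#' `SD1` and `SD2` are the dispersions across and along the line of identity
#' of the lagged scatter (rr_i, rr_{i+1}): `SD1 = sd((rr_{i+1} - rr_i) /
#' sqrt(2))`, `SD2 = sd((rr_{i+1} + rr_i) / sqrt(2))`. Units ms.
#'
#' @param rr_s RR intervals in seconds (>= 3 values).
#' @return named numeric vector `SD1`, `SD2`, `SD1_SD2` (`SD1_SD2` is `NA`
#'   when `SD2 = 0`).
#' @export
poincare <- function(rr_s) {
  out <- stats::setNames(rep(NA_real_, 3), c("SD1", "SD2", "SD1_SD2"))
  rr_s <- rr_s[is.finite(rr_s)]
  if (length(rr_s) < 3L) return(out)
  rr <- rr_s * 1000
  a <- rr[-length(rr)]
  b <- rr[-1]
  out["SD1"] <- stats::sd((b - a) / sqrt(2))
  out["SD2"] <- stats::sd((b + a) / sqrt(2))
  out["SD1_SD2"] <- if (out["SD2"] > 0) out["SD1"] / out["SD2"] else NA_real_
  out
}
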
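# Nonlinear HRV measures: DFA, entropies, RQA, largest Lyapunov exponent and
# correlation dimension. All operate on a single window's RR sequence and are
# written against explicit definitions so they can be validated against naive
# re-implementations on small instances.

#' Time-delay embedding
#'
#' @param x numeric series.
#' @param m embedding dimension.
#' @param delay embedding delay in samples.
#' @return matrix with one embedded point per row (`length(x) - (m - 1) *
#'   delay` rows, `m` columns), or `NULL` when the series is too short.
#' @keywords internal
#' @export
takens_embed <- function(x, m, delay = 1L) {
  n <- length(x) - (m - 1L) * delay
  if (n < 1L) return(NULL)
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * delay, `+`)
  matrix(x[idx], nrow = n, ncol = m)
}

# full Euclidean distance matrix between embedding rows
embed_dist <- function(E) {
  as.matrix(stats::dist(E))
}

#' Detrended fluctuation analysis exponents
#'
#' Integrates the mean-centred series, splits the profile into
#' non-overlapping boxes, removes a linear trend per box and measures the RMS
#' fluctuation `F(n)` per box size. `alpha1` is the log-log least-squares
#' slope over box sizes 4-16 and `alpha2` over 16-64 — the conventional
#' short- and long-range HRV scaling ranges.
#'
#' @param x numeric series (RR intervals; units cancel).
#' @param short_range,long_range integer box-size bounds for the two fits.
#' @return named numeric vector `alpha1`, `alpha2`; an exponent is `NA` when
#'   the series is too short for its range (fewer than 20 samples for
#'   `alpha1`, 130 for `alpha2`) or when the fluctuations degenerate to zero.
#' @examples
#' dfa(rnorm(1000))
#' @export
dfa <- function(x, short_range = c(4L, 16L), long_range = c(16L, 64L)) {
  out <- c(alpha1 = NA_real_, alpha2 = NA_real_)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L) return(out)
  y <- cumsum(x - mean(x))

  fluct <- function(box) {
    k <- floor(n / box)
    if (k < 2L) return(NA_real_)
    use <- y[seq_len(k * box)]
    seg <- matrix(use, nrow = box)
    tt <- seq_len(box)
    # per-box linear detrend via closed-form least squares
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    means <- colMeans(seg)
    slopes <- colSums(seg * tc) / denom
    resid <- seg - rep(means, each = box) - outer(tc, slopes)
    sqrt(mean(resid^2))
  }

  fit_alpha <- function(lo, hi) {
    sizes <- lo:hi
    f <- vapply(sizes, fluct, numeric(1))
    ok <- is.finite(f) & f > 0
    if (sum(ok) < 3L) return(NA_real_)
    stats::coef(stats::lm(log(f[ok]) ~ log(sizes[ok])))[[2]]
  }

  out["alpha1"] <- fit_alpha(short_range[1], short_range[2])
  if (n >= 130L) out["alpha2"] <- fit_alpha(long_range[1], long_range[2])
  out
}

#' Approximate and sample entropy
#'
#' Template-matching regularity statistics with Chebyshev distance,
#' embedding dimension `m` and tolerance `r` (default `0.2 * sd(x)`, floored
#' at `r_floor` so near-constant windows stay well defined). `ApEn` counts
#' self-matches; `SampEn = -log(A / B)` over distinct pairs without
#' self-matches.
#'
#' @param x numeric series (>= 60 values for windowed use; shorter input is
#'   accepted for testing).
#' @param m template length (default 2).
#' @param r tolerance in the units of `x`; default `0.2 * sd(x)`.
#' @param r_floor minimum tolerance (default 0.001, i.e. 1 ms for RR in
#'   seconds, 1 ms when `x` is already in ms-scaled units of SD ~ 1).
#' @return named numeric vector `ApEn`, `SampEn` (`SampEn` is `NA` when no
#'   template pair matches at length `m`).
#' @export
entropies <- function(x, m = 2L, r = NULL, r_floor = 0.001) {
  out <- c(ApEn = NA_real_, SampEn = NA_real_)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < m + 2L) return(out)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  r <- max(r, r_floor)

  cheb_match <- function(dim) {
    E <- takens_embed(x, dim)
    nE <- nrow(E)
    D <- matrix(0, nE, nE)
    for (j in seq_len(dim)) {
      D <- pmax(D, abs(outer(E[, j], E[, j], `-`)))
    }
    D <= r
  }

  Mm <- cheb_match(m)
  Mm1 <- cheb_match(m + 1L)

  # ApEn: self-matches included
  nm <- nrow(Mm)
  nm1 <- nrow(Mm1)
  phi_m <- mean(log(rowSums(Mm) / nm))
  phi_m1 <- mean(log(rowSums(Mm1) / nm1))
  out["ApEn"] <- phi_m - phi_m1

  # SampEn: distinct pairs, no self-matches; templates of length m restricted
  # to the first n - m positions so every template has an (m+1)-extension
  Mm_trunc <- Mm[seq_len(nm1), seq_len(nm1), drop = FALSE]
  B <- (sum(Mm_trunc) - nm1) / 2
  A <- (sum(Mm1) - nm1) / 2
  out["SampEn"] <- if (B > 0 && A > 0) -log(A / B) else if (B > 0 && A == 0) {
    NA_real_
  } else {
    NA_real_
  }
  out
}

#' Recurrence quantification analysis of one window
#'
#' Embeds the series (default dimension 10, delay 1), thresholds pairwise
#' Euclidean distances at a radius chosen so the recurrence rate hits
#' `rec_target` (default 10%), and summarises the recurrence matrix with the
#' line of identity excluded: recurrence rate `REC`; determinism `DET`, mean
#' and maximum diagonal-line length `L` and `Lmax` and diagonal-length
#' Shannon entropy `ENT` from diagonal lines of length >= `lmin`; laminarity
#' `LAM` and trapping time `TT` from vertical lines of length >= `vmin`.
#'
#' @param x numeric series (>= 100 values for windowed use).
#' @param m,delay embedding dimension and delay.
#' @param rec_target target recurrence rate used to set the radius when
#'   `radius` is `NULL`.
#' @param radius optional fixed recurrence radius.
#' @param lmin,vmin minimum diagonal / vertical line lengths.
#' @return named numeric vector `REC`, `L`, `TT`, `DET`, `LAM`, `ENT`,
#'   `Lmax`; all `NA` when the series is too short to embed at least 10
#'   points.
#' @export
rqa <- function(x, m = 10L, delay = 1L, rec_target = 0.1, radius = NULL,
                lmin = 2L, vmin = 2L) {
  out <- stats::setNames(
    rep(NA_real_, 7),
    c("REC", "L", "TT", "DET", "LAM", "ENT", "Lmax")
  )
  x <- x[is.finite(x)]
  E <- takens_embed(x, m, delay)
  if (is.null(E) || nrow(E) < 10L) return(out)
  N <- nrow(E)
  D <- embed_dist(E)
  off <- row(D) != col(D)
  if (is.null(radius)) {
    radius <- stats::quantile(D[off], rec_target, names = FALSE)
  }
  R <- D <= radius
  diag(R) <- FALSE

  n_rec <- sum(R)
  out["REC"] <- n_rec / (N * (N - 1))
  if (n_rec == 0) {
    out[c("L", "TT", "DET", "LAM", "ENT", "Lmax")] <-
      c(NA, NA, 0, 0, NA, 0)
    return(out)
  }

  # diagonal line census (both triangles; the matrix is symmetric so the
  # negative offsets mirror the positive ones)
  diag_lengths <- integer(0)
  for (k in seq_len(N - 1L)) {
    v <- R[cbind(seq_len(N - k), seq_len(N - k) + k)]
    r <- rle(v)
    diag_lengths <- c(diag_lengths, r$lengths[r$values])
  }
  diag_lengths <- rep(diag_lengths, 2L)
  dl <- diag_lengths[diag_lengths >= lmin]
  out["DET"] <- sum(dl) / n_rec
  if (length(dl)) {
    out["L"] <- mean(dl)
    out["Lmax"] <- max(dl)
    pr <- table(dl) / length(dl)
    out["ENT"] <- -sum(pr * log(pr))
  } else {
    out["L"] <- 0
    out["Lmax"] <- 0
    out["ENT"] <- 0
  }

  # vertical line census over all columns
  vert_lengths <- integer(0)
  for (j in seq_len(N)) {
    r <- rle(R[, j])
    vert_lengths <- c(vert_lengths, r$lengths[r$values])
  }
  vl <- vert_lengths[vert_lengths >= vmin]
  out["LAM"] <- sum(vl) / n_rec
  out["TT"] <- if (length(vl)) mean(vl) else 0
  out
}

#' Largest Lyapunov exponent (Rosenstein's method)
#'
#' Embeds the series, pairs every point with its nearest neighbour at least
#' `theiler` samples away in time, and tracks the mean log divergence of the
#' pairs over `max_steps` steps; the exponent is the least-squares slope of
#' that curve over `fit_steps` (nats per sample).
#'
#' @param x numeric series (>= 200 values for windowed use; shorter accepted
#'   for testing).
#' @param m,delay embedding dimension and delay.
#' @param theiler temporal exclusion window for neighbour search.
#' @param max_steps divergence horizon in samples.
#' @param fit_steps integer steps of the divergence curve used for the slope
#'   fit.
#' @return scalar exponent, or `NA` when no valid neighbour pair exists or
#'   the divergence curve degenerates.
#' @export
lle <- function(x, m = 10L, delay = 1L, theiler = 10L, max_steps = 15L,
                fit_steps = 0:7) {
  x <- x[is.finite(x)]
  E <- takens_embed(x, m, delay)
  if (is.null(E) || nrow(E) < theiler + 5L) return(NA_real_)
  N <- nrow(E)
  D <- embed_dist(E)
  excl <- abs(row(D) - col(D)) <= theiler
  D[excl] <- Inf
  nn <- apply(D, 1L, which.min)
  d0 <- D[cbind(seq_len(N), nn)]
  valid0 <- is.finite(d0) & d0 > 0
  if (!any(valid0)) return(NA_real_)

  steps <- 0:max_steps
  mean_log <- rep(NA_real_, length(steps))
  for (si in seq_along(steps)) {
    k <- steps[si]
    i <- which(valid0 & seq_len(N) + k <= N & nn + k <= N)
    if (!length(i)) next
    dk <- sqrt(rowSums((E[i + k, , drop = FALSE] -
                          E[nn[i] + k, , drop = FALSE])^2))
    pos <- dk > 0
    if (any(pos)) mean_log[si] <- mean(log(dk[pos]))
  }
  use <- steps %in% fit_steps & is.finite(mean_log)
  if (sum(use) < 3L) return(NA_real_)
  stats::coef(stats::lm(mean_log[use] ~ steps[use]))[[2]]
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums `C(r)` (fraction of point pairs closer than `r`, pairs
#' within `theiler` samples in time excluded) over log-spaced radii; the
#' dimension is the least-squares slope of `log C` vs `log r` over the
#' scaling region, taken as the radii where `C(r)` lies in `c_range`.
#'
#' @param x numeric series (>= 200 values for windowed use; shorter accepted
#'   for testing).
#' @param m,delay embedding dimension and delay.
#' @param theiler temporal exclusion window.
#' @param n_radii number of log-spaced radii.
#' @param c_range correlation-sum bounds defining the scaling region.
#' @return scalar dimension estimate, or `NA` when fewer than 3 radii fall in
#'   the scaling region (including constant input).
#' @export
correlation_dimension <- function(x, m = 10L, delay = 1L, theiler = 10L,
                                  n_radii = 24L, c_range = c(0.005, 0.5)) {
  x <- x[is.finite(x)]
  E <- takens_embed(x, m, delay)
  if (is.null(E) || nrow(E) < theiler + 10L) return(NA_real_)
  N <- nrow(E)
  D <- embed_dist(E)
  keep <- abs(row(D) - col(D)) > theiler & row(D) < col(D)
  d <- D[keep]
  d <- d[d > 0]
  if (length(d) < 50L) return(NA_real_)
  radii <- exp(seq(log(stats::quantile(d, 0.01, names = FALSE)),
                   log(max(d)), length.out = n_radii))
  n_pairs <- sum(keep)
  cs <- vapply(radii, function(r) sum(d < r) / n_pairs, numeric(1))
  sel <- cs >= c_range[1] & cs <= c_range[2] & cs > 0
  if (sum(sel) < 3L) return(NA_real_)
  stats::coef(stats::lm(log(cs[sel]) ~ log(radii[sel])))[[2]]
}
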
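# Independent naive re-implementations used as oracles. Deliberately written
# as plain loops over the definitions, sharing no code with the package.

oracle_time_domain <- function(rr_s) {
  rr <- rr_s * 1000
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  nn50 <- 0
  for (i in seq_along(d)) if (abs(d[i]) > 50) nn50 <- nn50 + 1
  c(
    NN50 = nn50,
    pNN50 = 100 * nn50 / (n - 1),
    SDNN = sqrt(sum((rr - mean(rr))^2) / (n - 1)),
    RMSSD = sqrt(sum(d^2) / length(d)),
    SDSD = sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
    RRMean = mean(rr),
    RRMin = min(rr),
    RRMax = max(rr),
    RRVar = sum((rr - mean(rr))^2) / (n - 1)
  )
}

# Poincare dispersions via explicit 45-degree rotation of the lagged scatter
oracle_poincare <- function(rr_s) {
  rr <- rr_s * 1000
  x <- rr[-length(rr)]
  y <- rr[-1]
  u <- (y - x) / sqrt(2)   # across identity line
  v <- (y + x) / sqrt(2)   # along identity line
  c(SD1 = stats::sd(u), SD2 = stats::sd(v))
}

# Direct evaluation of the Lomb normalised periodogram at given frequencies,
# rescaled like the package's estimator (integral equals variance)
oracle_lomb <- function(t, x, freq) {
  xc <- x - mean(x)
  p <- numeric(length(freq))
  for (j in seq_along(freq)) {
    w <- 2 * pi * freq[j]
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    cs <- ss <- cc <- s2 <- 0
    for (i in seq_along(t)) {
      a <- w * (t[i] - tau)
      cs <- cs + xc[i] * cos(a)
      ss <- ss + xc[i] * sin(a)
      cc <- cc + cos(a)^2
      s2 <- s2 + sin(a)^2
    }
    p[j] <- 0.5 * (cs^2 / cc + ss^2 / s2)
  }
  df <- freq[2] - freq[1]
  integral <- sum((p[-1] + p[-length(p)]) / 2) * df
  p * stats::var(x) / integral
}

# O(n^2) template-counting entropies (Chebyshev distance)
oracle_entropies <- function(x, m = 2L, r) {
  n <- length(x)
  count_matches <- function(dim, self) {
    nv <- n - dim + 1
    cnt <- numeric(nv)
    for (i in seq_len(nv)) {
      for (j in seq_len(nv)) {
        if (!self && i == j) next
        dmax <- 0
        for (k in 0:(dim - 1)) {
          dd <- abs(x[i + k] - x[j + k])
          if (dd > dmax) dmax <- dd
        }
        if (dmax <= r) cnt[i] <- cnt[i] + 1
      }
    }
    cnt
  }
  phi <- function(dim) {
    cnt <- count_matches(dim, self = TRUE)
    mean(log(cnt / (n - dim + 1)))
  }
  apen <- phi(m) - phi(m + 1)
  # SampEn: m-templates truncated so each has an (m+1)-extension
  nv1 <- n - m
  B <- 0
  A <- 0
  for (i in seq_len(nv1 - 1)) {
    for (j in (i + 1):nv1) {
      dmax <- 0
      for (k in 0:(m - 1)) {
        dd <- abs(x[i + k] - x[j + k])
        if (dd > dmax) dmax <- dd
      }
      if (dmax <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  sampen <- if (B > 0 && A > 0) -log(A / B) else NA_real_
  c(ApEn = apen, SampEn = sampen)
}

# Explicit recurrence-matrix census with the line of identity excluded
oracle_rqa <- function(x, m, radius, lmin = 2L, vmin = 2L) {
  N <- length(x) - m + 1
  E <- matrix(0, N, m)
  for (i in seq_len(N)) E[i, ] <- x[i:(i + m - 1)]
  R <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      R[i, j] <- sqrt(sum((E[i, ] - E[j, ])^2)) <= radius
    }
  }
  n_rec <- sum(R)
  rec <- n_rec / (N * (N - 1))
  dlen <- integer(0)
  for (k in c(-(N - 1):-1, 1:(N - 1))) {
    run <- 0
    for (i in seq_len(N)) {
      j <- i + k
      inside <- j >= 1 && j <= N
      v <- inside && R[i, j]
      if (v) {
        run <- run + 1
      } else {
        if (run > 0) dlen <- c(dlen, run)
        run <- 0
      }
    }
    if (run > 0) dlen <- c(dlen, run)
  }
  dl <- dlen[dlen >= lmin]
  det <- if (n_rec > 0) sum(dl) / n_rec else NA_real_
  ent <- if (length(dl)) {
    pr <- table(dl) / length(dl)
    -sum(pr * log(pr))
  } else {
    0
  }
  vlen <- integer(0)
  for (j in seq_len(N)) {
    run <- 0
    for (i in seq_len(N)) {
      if (R[i, j]) {
        run <- run + 1
      } else {
        if (run > 0) vlen <- c(vlen, run)
        run <- 0
      }
    }
    if (run > 0) vlen <- c(vlen, run)
  }
  vl <- vlen[vlen >= vmin]
  c(
    REC = rec,
    L = if (length(dl)) mean(dl) else 0,
    TT = if (length(vl)) mean(vl) else 0,
    DET = det,
    LAM = if (n_rec > 0) sum(vl) / n_rec else NA_real_,
    ENT = ent,
    Lmax = if (length(dl)) max(dl) else 0
  )
}

# Pairwise-loop Dunn index
oracle_dunn <- function(X, labels) {
  u <- unique(labels)
  a <- which(labels == u[1])
  b <- which(labels == u[2])
  dd <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  inter <- Inf
  for (i in a) for (j in b) inter <- min(inter, dd(i, j))
  diam <- 0
  for (g in list(a, b)) {
    if (length(g) > 1) {
      for (i in seq_along(g)) {
        for (j in seq_along(g)) {
          if (j > i) diam <- max(diam, dd(g[i], g[j]))
        }
      }
    }
  }
  if (diam == 0) Inf else inter / diam
}

# Loop-based DFA fluctuation + per-range slope using lm on each box size
oracle_dfa_alpha <- function(x, lo, hi) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- lo:hi
  fs <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    k <- floor(n / s)
    ss <- 0
    cnt <- 0
    for (b in seq_len(k)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      tt <- seq_len(s)
      fit <- stats::lm(seg ~ tt)
      ss <- ss + sum(stats::resid(fit)^2)
      cnt <- cnt + s
    }
    fs[si] <- sqrt(ss / cnt)
  }
  ok <- fs > 0
  stats::coef(stats::lm(log(fs[ok]) ~ log(sizes[ok])))[[2]]
}

# Loop-based Rosenstein divergence-curve estimator
oracle_lle <- function(x, m, theiler, max_steps, fit_steps) {
  N <- length(x) - m + 1
  E <- matrix(0, N, m)
  for (i in seq_len(N)) E[i, ] <- x[i:(i + m - 1)]
  dd <- function(i, j) sqrt(sum((E[i, ] - E[j, ])^2))
  nn <- integer(N)
  d0 <- numeric(N)
  for (i in seq_len(N)) {
    best <- Inf
    bj <- NA_integer_
    for (j in seq_len(N)) {
      if (abs(i - j) <= theiler) next
      dij <- dd(i, j)
      if (dij < best) {
        best <- dij
        bj <- j
      }
    }
    nn[i] <- bj
    d0[i] <- best
  }
  steps <- 0:max_steps
  y <- rep(NA_real_, length(steps))
  for (si in seq_along(steps)) {
    k <- steps[si]
    acc <- c()
    for (i in seq_len(N)) {
      if (!is.finite(d0[i]) || d0[i] <= 0) next
      if (i + k > N || nn[i] + k > N) next
      dk <- dd(i + k, nn[i] + k)
      if (dk > 0) acc <- c(acc, log(dk))
    }
    if (length(acc)) y[si] <- mean(acc)
  }
  use <- steps %in% fit_steps & is.finite(y)
  stats::coef(stats::lm(y[use] ~ steps[use]))[[2]]
}

# Loop-based Grassberger-Procaccia estimator mirroring the definition
oracle_cd <- function(x, m, theiler, n_radii = 24L, c_range = c(0.005, 0.5)) {
  N <- length(x) - m + 1
  E <- matrix(0, N, m)
  for (i in seq_len(N)) E[i, ] <- x[i:(i + m - 1)]
  d <- c()
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (j - i <= theiler) next
      dij <- sqrt(sum((E[i, ] - E[j, ])^2))
      if (dij > 0) d <- c(d, dij)
    }
  }
  radii <- exp(seq(log(stats::quantile(d, 0.01, names = FALSE)),
                   log(max(d)), length.out = n_radii))
  n_pairs <- length(d)
  cs <- numeric(n_radii)
  for (ri in seq_len(n_radii)) {
    cnt <- 0
    for (v in d) if (v < radii[ri]) cnt <- cnt + 1
    cs[ri] <- cnt / n_pairs
  }
  sel <- cs >= c_range[1] & cs <= c_range[2] & cs > 0
  stats::coef(stats::lm(log(cs[sel]) ~ log(radii[sel])))[[2]]
}
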
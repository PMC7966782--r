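#' Enumerate all three-feature combinations
#'
#' The exhaustive search examines every unordered triple of features, so with
#' the full 32-feature set there are `choose(32, 3) = 4960` combinations.
#'
#' @param n_features number of features (>= 3).
#' @return integer matrix with one sorted triple per row, lexicographic
#'   order.
#' @examples
#' nrow(enumerate_combinations(32))
#' @export
enumerate_combinations <- function(n_features) {
  if (n_features < 3) stop("need at least 3 features", call. = FALSE)
  t(utils::combn(as.integer(n_features), 3L))
}

#' Column-standardize a feature-space matrix
#'
#' Centres each column and scales it by its sample (n - 1) standard
#' deviation. Constant columns cannot be scaled and are set to zero, with a
#' warning.
#'
#' @param X numeric matrix (complete rows).
#' @param warn warn on constant columns (default `TRUE`).
#' @return matrix of the same shape with column means 0 and SDs 1 (0 for
#'   constant columns).
#' @export
standardize_features <- function(X, warn = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  zero <- sdv == 0
  if (any(zero) && warn) {
    warning("constant column(s) set to zero during standardization",
            call. = FALSE)
  }
  sdv[zero] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Z[, zero] <- 0
  Z
}

#' Dunn's index of a two-cluster partition
#'
#' Ratio of the minimum inter-cluster distance (single linkage) to the
#' maximum intra-cluster diameter, both Euclidean. Degenerate partitions
#' where both clusters have zero diameter return `Inf`.
#'
#' @param X numeric matrix of points (ignored when `dist_matrix` is given).
#' @param labels cluster labels taking exactly two values.
#' @param dist_matrix optional precomputed full distance matrix.
#' @return non-negative scalar (possibly `Inf`).
#' @export
dunn_index <- function(X, labels, dist_matrix = NULL) {
  u <- unique(labels)
  if (length(u) != 2L) stop("labels must define exactly 2 clusters",
                            call. = FALSE)
  D <- if (is.null(dist_matrix)) as.matrix(stats::dist(X)) else dist_matrix
  a <- which(labels == u[1])
  b <- which(labels == u[2])
  inter <- min(D[a, b])
  diam <- function(idx) if (length(idx) < 2L) 0 else max(D[idx, idx])
  intra <- max(diam(a), diam(b))
  if (intra == 0) return(Inf)
  inter / intra
}

#' DBSCAN clustering on a precomputed distance matrix
#'
#' Plain density-based clustering: points with at least `minpts` neighbours
#' within `eps` (self included) are core points; clusters are the connected
#' components of core points under eps-reachability, with border points
#' attached to a neighbouring core cluster and everything else labelled
#' noise (0).
#'
#' @param D full symmetric distance matrix.
#' @param eps neighbourhood radius.
#' @param minpts minimum neighbourhood size for a core point (default 6,
#'   twice the feature-space dimensionality).
#' @return integer labels, `0` for noise.
#' @export
dbscan_cluster <- function(D, eps, minpts = 6L) {
  n <- nrow(D)
  nb <- D <= eps
  core <- rowSums(nb) >= minpts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      reach <- which(matrixStatsAny(nb[frontier, , drop = FALSE]))
      new_pts <- reach[labels[reach] == 0L]
      labels[new_pts] <- cl
      frontier <- new_pts[core[new_pts]]
    }
  }
  labels
}

# column-wise any() over a logical matrix
matrixStatsAny <- function(M) colSums(M) > 0L

#' Gaussian-mixture clustering by EM
#'
#' Fits a k-component full-covariance Gaussian mixture by
#' expectation-maximization with seeded restarts (first restart initialised
#' from k-means, the rest from random responsibilities) and returns the
#' maximum-posterior labels of the best fit by log-likelihood.
#'
#' @param X numeric matrix of points.
#' @param k number of components (default 2).
#' @param seed integer seed controlling the restarts.
#' @param restarts number of EM restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return integer labels in `1:k`, or `NULL` when every restart degenerates.
#' @export
gmm_cluster <- function(X, k = 2L, seed = 1L, restarts = 5L, tol = 1e-6,
                        max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < k * (d + 1L)) return(NULL)
  reg <- 1e-6 * mean(apply(X, 2L, stats::var)) + 1e-12
  tX <- t(X)

  log_dens <- function(mu, S) {
    ch <- tryCatch(chol(S + diag(reg, d)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Y <- forwardsolve(t(ch), tX - mu)
    -0.5 * colSums(Y^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  }

  run_em <- function(resp) {
    ll_old <- -Inf
    labels_old <- NULL
    stable <- 0L
    for (iter in seq_len(max_iter)) {
      nk <- colSums(resp)
      if (any(nk < d + 1)) return(NULL)
      w <- nk / n
      logd <- matrix(0, n, k)
      for (j in seq_len(k)) {
        mu <- colSums(resp[, j] * X) / nk[j]
        Xc <- sweep(X, 2L, mu)
        S <- crossprod(Xc * resp[, j], Xc) / nk[j]
        ld <- log_dens(mu, S)
        if (is.null(ld)) return(NULL)
        logd[, j] <- ld + log(w[j])
      }
      mx <- do.call(pmax, lapply(seq_len(k), function(j) logd[, j]))
      lse <- mx + log(rowSums(exp(logd - mx)))
      resp <- exp(logd - lse)
      ll <- sum(lse)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        break
      }
      # hard assignments usually freeze long before the likelihood
      # tolerance; three stable iterations end the run
      labels_new <- max.col(logd)
      if (identical(labels_new, labels_old)) {
        stable <- stable + 1L
        if (stable >= 3L) break
      } else {
        stable <- 0L
      }
      labels_old <- labels_new
      ll_old <- ll
    }
    list(ll = ll, labels = max.col(logd))
  }

  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      resp <- if (r == 1L) {
        km <- tryCatch(stats::kmeans(X, k, nstart = 5L),
                       error = function(e) NULL)
        if (is.null(km)) next
        outer(km$cluster, seq_len(k), `==`) * 1
      } else {
        rr <- matrix(stats::runif(n * k), n, k)
        rr / rowSums(rr)
      }
      fit <- run_em(resp)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
    if (is.null(best)) NULL else best$labels
  })
}

# Smaller-cluster membership under the convention that the smaller cluster is
# the candidate preictal interval. When the two clusters are equal-sized, the
# cluster whose last window lies nearer seizure onset is taken as "smaller",
# anchoring the candidate in time.
smaller_cluster <- function(labels, window_index) {
  u <- sort(unique(labels))
  stopifnot(length(u) == 2L)
  n1 <- sum(labels == u[1])
  n2 <- sum(labels == u[2])
  pick <- if (n1 != n2) {
    if (n1 < n2) u[1] else u[2]
  } else {
    if (max(window_index[labels == u[1]]) > max(window_index[labels == u[2]])) {
      u[1]
    } else {
      u[2]
    }
  }
  window_index[labels == pick]
}

new_cluster_solution <- function(combination, comb_names, method, labels,
                                 window_index, dunn) {
  sw <- smaller_cluster(labels, window_index)
  structure(
    list(
      combination = as.integer(combination),
      feature_names = comb_names,
      method = method,
      labels = labels,
      window_index = window_index,
      smaller_windows = sort(sw),
      n_smaller = length(sw),
      dunn = dunn
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "<cluster_solution> %s on (%s): smaller cluster %d windows, DI = %.4f\n",
    x$method, paste(x$feature_names, collapse = ", "), x$n_smaller, x$dunn
  ))
  invisible(x)
}

#' Run the clustering methods on one three-feature space
#'
#' Applies k-means, Ward agglomerative clustering and a Gaussian mixture at
#' `k = 2`, plus DBSCAN at each radius in `eps` (`MinPts = 6`), to a
#' standardized windows x 3 matrix. DBSCAN runs are retained only when they
#' yield exactly two clusters and no noise points; the partitioning methods
#' always yield two clusters unless they degenerate. Each retained solution
#' carries its smaller-cluster membership and Dunn's index, computed on the
#' standardized space.
#'
#' @param Z standardized complete-case matrix (windows x 3).
#' @param window_index window index of each row of `Z`.
#' @param combination integer feature-index triple (bookkeeping only).
#' @param comb_names feature names of the triple.
#' @param methods subset of `c("KM", "AH", "GMM", "DBSCAN_1", "DBSCAN_2",
#'   "DBSCAN_3", "DBSCAN_4")`.
#' @param seed integer seed for the stochastic methods (k-means restarts,
#'   EM restarts).
#' @param minpts DBSCAN core-point threshold.
#' @return list of `cluster_solution` objects (possibly empty).
#' @export
run_clusterers <- function(Z, window_index, combination = 1:3,
                           comb_names = colnames(Z),
                           methods = c("KM", "AH", "GMM", "DBSCAN_1",
                                       "DBSCAN_2", "DBSCAN_3", "DBSCAN_4"),
                           seed = 1L, minpts = 6L) {
  stopifnot(nrow(Z) == length(window_index))
  methods <- match.arg(methods, several.ok = TRUE)
  if (nrow(Z) < 2L * minpts) return(list())
  if (all(apply(Z, 2L, function(col) length(unique(col)) == 1L))) {
    return(list())  # all rows identical: nothing to partition
  }
  D <- as.matrix(stats::dist(Z))
  out <- list()
  add <- function(method, labels) {
    if (is.null(labels)) return()
    u <- unique(labels)
    if (length(u) != 2L || any(labels == 0L)) return()
    if (min(table(labels)) < 1L) return()
    di <- dunn_index(Z, labels, dist_matrix = D)
    out[[length(out) + 1L]] <<- new_cluster_solution(
      combination, comb_names, method, labels, window_index, di
    )
  }

  if ("KM" %in% methods) {
    km <- with_local_seed(seed, tryCatch(
      stats::kmeans(Z, 2L, nstart = 10L, iter.max = 50L),
      error = function(e) NULL
    ))
    if (!is.null(km)) add("KM", km$cluster)
  }
  if ("AH" %in% methods) {
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
    add("AH", stats::cutree(hc, k = 2L))
  }
  for (eps_i in 1:4) {
    mname <- paste0("DBSCAN_", eps_i)
    if (!mname %in% methods) next
    add(mname, dbscan_cluster(D, eps = eps_i, minpts = minpts))
  }
  if ("GMM" %in% methods) {
    add("GMM", gmm_cluster(Z, k = 2L, seed = seed + 1L))
  }
  out
}

#' First acceptance gate for clustering solutions
#'
#' A candidate two-cluster solution is accepted when its smaller cluster
#' carries at least `min_samples` windows (with the 5-s step, 20 windows is
#' 1.58 min of information) and its Dunn's index reaches `di_threshold`.
#' Noisy or non-two-cluster DBSCAN runs were already discarded upstream.
#'
#' @param candidates list of `cluster_solution` objects.
#' @param min_samples minimum smaller-cluster size (default 20).
#' @param di_threshold minimum Dunn's index (default 0.15).
#' @return the accepted subset, in input order.
#' @export
accept_solutions <- function(candidates, min_samples = 20L,
                             di_threshold = 0.15) {
  Filter(function(s) {
    s$n_smaller >= min_samples && !is.na(s$dunn) && s$dunn >= di_threshold
  }, candidates)
}

#' Exhaustive three-feature clustering scan of one seizure
#'
#' For every feature triple: drop windows missing any of the three features,
#' standardize, run the clustering methods, and keep the solutions passing
#' the acceptance gate.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param combinations integer matrix of feature-index triples (default all
#'   `choose(F, 3)` over the matrix's features).
#' @param methods clustering methods, see [run_clusterers()].
#' @param seed integer seed.
#' @param min_samples,di_threshold acceptance-gate parameters, see
#'   [accept_solutions()].
#' @param min_rows minimum complete-case rows required to attempt clustering.
#' @return list with `accepted` (list of `cluster_solution`), `n_combinations`
#'   scanned, and `n_candidates` evaluated.
#' @export
scan_seizure <- function(fm, combinations = NULL,
                         methods = c("KM", "AH", "GMM", "DBSCAN_1",
                                     "DBSCAN_2", "DBSCAN_3", "DBSCAN_4"),
                         seed = 1L, min_samples = 20L, di_threshold = 0.15,
                         min_rows = 12L) {
  stopifnot(inherits(fm, "feature_matrix"))
  F_n <- ncol(fm$values)
  if (is.null(combinations)) combinations <- enumerate_combinations(F_n)
  accepted <- list()
  n_candidates <- 0L
  for (ci in seq_len(nrow(combinations))) {
    comb <- combinations[ci, ]
    X <- fm$values[, comb, drop = FALSE]
    keep <- stats::complete.cases(X)
    if (sum(keep) < min_rows) next
    Z <- suppressWarnings(standardize_features(X[keep, , drop = FALSE]))
    sols <- run_clusterers(
      Z, window_index = which(keep), combination = comb,
      comb_names = fm$feature_names[comb], methods = methods,
      seed = derive_seed(seed, ci)
    )
    n_candidates <- n_candidates + length(sols)
    accepted <- c(accepted,
                  accept_solutions(sols, min_samples, di_threshold))
  }
  list(
    accepted = accepted,
    n_combinations = nrow(combinations),
    n_candidates = n_candidates
  )
}
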
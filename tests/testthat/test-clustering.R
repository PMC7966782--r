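test_that("the triple enumeration has binomial size and sorted rows", {
  c32 <- enumerate_combinations(32)
  expect_equal(nrow(c32), 4960)
  expect_equal(nrow(enumerate_combinations(3)), 1)
  expect_equal(nrow(enumerate_combinations(8)), 56)
  expect_true(all(c32[, 1] < c32[, 2] & c32[, 2] < c32[, 3]))
  expect_false(any(duplicated(c32)))
})

test_that("standardization uses the sample-SD convention", {
  Z <- standardize_features(cbind(c(1, 2, 3)))
  expect_equal(as.numeric(Z), c(-1, 0, 1))
  expect_warning(Zc <- standardize_features(cbind(1:5, rep(2, 5))),
                 "constant")
  expect_true(all(Zc[, 2] == 0))
  set.seed(71)
  Zr <- standardize_features(matrix(rnorm(60), ncol = 3))
  expect_true(all(abs(colMeans(Zr)) < 1e-12))
  expect_equal(apply(Zr, 2, sd), rep(1, 3), ignore_attr = TRUE)
})

test_that("Dunn's index reproduces analytic and brute-force values", {
  X <- rbind(c(0, 0, 0), c(0, 0, 1), c(10, 0, 0), c(10, 0, 1))
  expect_equal(dunn_index(X, c(1, 1, 2, 2)), 10)
  # both clusters collapsed to points: infinite sentinel
  X2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(5, 5, 5), c(5, 5, 5))
  expect_identical(dunn_index(X2, c(1, 1, 2, 2)), Inf)
  set.seed(72)
  X3 <- matrix(rnorm(180), ncol = 3)
  lab <- rep(1:2, each = 30)
  expect_equal(dunn_index(X3, lab), oracle_dunn(X3, lab))
})

test_that("all partitioning methods find a well-separated planted minority", {
  tb <- two_blobs(100, 30, sep = 10, seed = 73)
  Z <- standardize_features(tb$X)
  sols <- run_clusterers(Z, seq_len(nrow(Z)), methods = c("KM", "AH", "GMM"),
                         seed = 1)
  expect_length(sols, 3)
  for (s in sols) {
    expect_setequal(s$smaller_windows, tb$small)
    expect_equal(s$n_smaller, 30)
  }
})

test_that("DBSCAN declines single blobs and noisy solutions", {
  set.seed(74)
  X <- matrix(rnorm(300), ncol = 3)
  Z <- standardize_features(X)
  expect_length(run_clusterers(Z, seq_len(nrow(Z)), methods = "DBSCAN_2",
                               seed = 1), 0)
  # blob plus isolated outliers: DBSCAN labels them noise -> discarded
  X2 <- rbind(matrix(rnorm(300, sd = 0.1), ncol = 3),
              matrix(c(50, 50, 50, -50, 50, -50, 50, -50, -50),
                     ncol = 3, byrow = TRUE))
  labels <- dbscan_cluster(as.matrix(dist(standardize_features(X2))),
                           eps = 1, minpts = 6)
  expect_true(any(labels == 0))
  Z2 <- standardize_features(X2)
  expect_length(run_clusterers(Z2, seq_len(nrow(Z2)), methods = "DBSCAN_1",
                               seed = 1), 0)
})

test_that("two separated blobs yield a clean two-cluster DBSCAN solution", {
  tb <- two_blobs(60, 25, sep = 12, seed = 75)
  Z <- standardize_features(tb$X)
  sols <- run_clusterers(Z, seq_len(nrow(Z)), methods = "DBSCAN_1", seed = 1)
  expect_length(sols, 1)
  expect_setequal(sols[[1]]$smaller_windows, tb$small)
})

test_that("the acceptance gate enforces size and Dunn thresholds", {
  mk <- function(n_small, di) {
    structure(list(combination = 1:3, feature_names = letters[1:3],
                   method = "KM", labels = NULL,
                   window_index = seq_len(n_small + 50),
                   smaller_windows = seq_len(n_small),
                   n_smaller = n_small, dunn = di),
              class = "cluster_solution")
  }
  expect_length(accept_solutions(list(mk(66, 0.1576))), 1)
  expect_length(accept_solutions(list(mk(19, 0.9))), 0)
  expect_length(accept_solutions(list(mk(200, 0.1499))), 0)
  expect_length(accept_solutions(list(mk(20, 0.15))), 1)  # inclusive gates
})

test_that("gate acceptance is monotone in the Dunn threshold", {
  set.seed(76)
  mk <- function(n_small, di) {
    structure(list(n_smaller = n_small, dunn = di),
              class = "cluster_solution")
  }
  sols <- lapply(1:50, function(i) mk(sample(5:100, 1), runif(1, 0, 0.5)))
  thresholds <- seq(0, 0.5, by = 0.05)
  kept <- lapply(thresholds, function(th)
    which(vapply(sols, function(s)
      length(accept_solutions(list(s), di_threshold = th)) == 1, logical(1))))
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("smaller-cluster identity is label-permutation invariant", {
  wi <- 1:50
  lab <- c(rep(1, 35), rep(2, 15))
  expect_identical(preictalHRV:::smaller_cluster(lab, wi), 36:50)
  expect_identical(preictalHRV:::smaller_cluster(3 - lab, wi), 36:50)
  # equal sizes: the cluster ending nearer onset (higher window index) wins
  lab_eq <- rep(c(1, 2), each = 25)
  expect_identical(preictalHRV:::smaller_cluster(lab_eq, wi), 26:50)
})

test_that("our EM mixture agrees with mclust on separated blobs", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  tb <- two_blobs(80, 30, sep = 8, seed = 77)
  lab <- gmm_cluster(tb$X, k = 2, seed = 1)
  mc <- Mclust(tb$X, G = 2, modelNames = "VVV", verbose = FALSE)
  agree <- max(mean(lab == mc$classification),
               mean(lab == 3 - mc$classification))
  expect_equal(agree, 1)
})

test_that("the scan is deterministic for a fixed seed", {
  out <- generate_rri(synth_config(rng_seed = 78))
  grid <- build_window_grid(240, 300, 120)
  fm <- extract_features(out$rri, grid,
                         features = c("SDNN", "RMSSD", "RRMean", "RRMax"))
  a <- scan_seizure(fm, methods = c("KM", "GMM"), seed = 9)
  b <- scan_seizure(fm, methods = c("KM", "GMM"), seed = 9)
  expect_equal(a$n_combinations, 4)
  expect_identical(a, b)
})
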
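test_that("DFA agrees with the loop-based oracle on a random window", {
  set.seed(51)
  x <- rnorm(300)
  a <- dfa(x)
  expect_equal(unname(a["alpha1"]), oracle_dfa_alpha(x, 4, 16),
               tolerance = 1e-9)
  expect_equal(unname(a["alpha2"]), oracle_dfa_alpha(x, 16, 64),
               tolerance = 1e-9)
})

test_that("DFA distinguishes white noise from its integral", {
  set.seed(52)
  white <- replicate(20, dfa(rnorm(1000))[["alpha1"]])
  brown <- replicate(20, dfa(cumsum(rnorm(1000)))[["alpha1"]])
  expect_gt(mean(white), 0.4)
  expect_lt(mean(white), 0.6)
  expect_gt(mean(brown), 1.4)
  expect_lt(mean(brown), 1.6)
})

test_that("too-short windows leave the respective DFA exponent missing", {
  a <- dfa(rnorm(60))
  expect_false(is.na(a["alpha1"]))
  expect_true(is.na(a["alpha2"]))
  expect_true(all(is.na(dfa(rnorm(10)))))
})

test_that("entropies match the O(n^2) template-counting oracle", {
  set.seed(53)
  x <- runif(300)
  r <- 0.2 * sd(x)
  e <- entropies(x, m = 2, r = r, r_floor = 0)
  o <- oracle_entropies(x, m = 2, r = r)
  expect_equal(unname(e["ApEn"]), unname(o["ApEn"]), tolerance = 1e-9)
  expect_equal(unname(e["SampEn"]), unname(o["SampEn"]), tolerance = 1e-9)
})

test_that("constant and strictly periodic series have zero sample entropy", {
  e_const <- entropies(rep(800, 100))
  expect_equal(unname(e_const["SampEn"]), 0)
  per <- rep(c(700, 900), 60)
  e_per <- entropies(per, r = 50)  # below half the amplitude gap
  expect_equal(unname(e_per["SampEn"]), 0)
})

test_that("RQA matches the explicit recurrence-matrix oracle exactly", {
  set.seed(54)
  x <- runif(150)
  E <- takens_embed(x, 10)
  D <- as.matrix(dist(E))
  radius <- quantile(D[row(D) != col(D)], 0.1, names = FALSE)
  got <- rqa(x, m = 10, radius = radius)
  want <- oracle_rqa(x, m = 10, radius = radius)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
})

test_that("a saturated recurrence matrix gives the degenerate RQA profile", {
  got <- rqa(rep(5, 40), m = 10, radius = 0.5)
  want <- oracle_rqa(rep(5, 40), m = 10, radius = 0.5)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
  expect_equal(unname(got["REC"]), 1)
  expect_equal(unname(got["Lmax"]), 40 - 10 + 1 - 1)  # N - 1 off the LOI
  # only the single-point corner diagonals fall below the 2-point line floor
  expect_gt(unname(got["DET"]), 0.99)
  expect_gt(unname(got["LAM"]), 0.99)
})

test_that("period-2 dynamics put all recurrences on alternating diagonals", {
  x <- rep(c(1, 2), 15)  # 30 points
  got <- rqa(x, m = 2, radius = 0.1)
  want <- oracle_rqa(x, m = 2, radius = 0.1)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
  expect_gt(unname(got["DET"]), 0.95)  # recurrences live on diagonal lines
})

test_that("the Lyapunov estimate separates periodic from chaotic dynamics", {
  per <- sin(2 * pi * (1:1000) / 25)
  expect_lte(lle(per, m = 10, theiler = 10, max_steps = 20,
                 fit_steps = 0:10), 0.05)
  # logistic map at r = 4: analytic exponent log(2) = 0.693 nats/step
  x <- numeric(1100)
  x[1] <- 0.3123
  for (i in 2:1100) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x <- x[101:1100]
  l <- lle(x, m = 2, theiler = 5, max_steps = 10, fit_steps = 0:5)
  expect_gt(l, 0.5)
  expect_lt(l, 0.9)
})

test_that("degenerate series leave LLE and CD missing", {
  expect_true(is.na(correlation_dimension(rep(1, 300))))
  expect_true(is.na(lle(rnorm(20))))
})

test_that("correlation dimension recovers manifold dimension", {
  # noiseless ramp: temporal neighbours are geometric neighbours, so the
  # Theiler window is dropped for this deterministic 1-D manifold
  expect_true(abs(correlation_dimension(seq(0, 1, length.out = 300),
                                        m = 10, theiler = 0) - 1) <= 0.2)
  set.seed(55)
  cd2 <- correlation_dimension(runif(1000), m = 2, theiler = 10)
  expect_gte(cd2, 1.7)
  expect_lte(cd2, 2.1)
})
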
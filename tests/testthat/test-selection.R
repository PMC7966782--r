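test_that("continuity follows the sequential-over-time rule", {
  expect_equal(classify_continuity(10:29, 1:100), "continuous")
  expect_equal(classify_continuity(c(5, 6, 9), 1:100), "discontinuous")
  # gaps caused solely by masked windows do not break continuity
  valid <- setdiff(1:100, c(7, 8))
  expect_equal(classify_continuity(c(5, 6, 9), valid), "continuous")
  expect_equal(classify_continuity(c(5, 6, 9), valid, strict = TRUE),
               "discontinuous")
})

test_that("the duration convention reproduces the printed pairs", {
  pairs <- rbind(
    c(20, 1.58), c(23, 1.83), c(43, 3.50), c(66, 5.42),
    c(110, 9.08), c(431, 35.83), c(970, 80.75)
  )
  for (i in seq_len(nrow(pairs))) {
    expect_identical(duration_minutes(pairs[i, 1], step_s = 5), pairs[i, 2])
  }
  expect_identical(duration_minutes(1), 0)
})

mk_sol <- function(windows, di = 0.3, method = "KM", comb = 1:3) {
  structure(
    list(combination = comb, feature_names = paste0("f", comb),
         method = method, labels = NULL, window_index = 1:3000,
         smaller_windows = windows, n_smaller = length(windows), dunn = di),
    class = "cluster_solution"
  )
}

test_that("selection prefers continuity, then size, then Dunn's index", {
  grid <- build_window_grid(240, 300, 5)
  cont30 <- mk_sol(1000:1029)
  disc100 <- mk_sol(c(200:250, 400:448))
  sel <- select_solution(list(disc100, cont30), grid, seizure_id = "s1")
  expect_equal(sel$solution$smaller_windows, 1000:1029)
  expect_equal(sel$continuity, "continuous")

  cont50 <- mk_sol(2000:2049)
  sel2 <- select_solution(list(cont30, cont50), grid)
  expect_equal(sel2$solution$n_smaller, 50)

  hi_di <- mk_sol(1000:1029, di = 0.9, method = "GMM")
  sel3 <- select_solution(list(cont30, hi_di), grid)
  expect_equal(sel3$solution$method, "GMM")

  expect_null(select_solution(list(), grid))
})

test_that("selection is invariant to candidate ordering", {
  grid <- build_window_grid(240, 300, 5)
  sols <- list(mk_sol(1000:1029), mk_sol(2000:2049),
               mk_sol(c(200:250, 400:448)), mk_sol(500:519, di = 0.8))
  a <- select_solution(sols, grid)
  b <- select_solution(rev(sols), grid)
  expect_identical(a$solution, b$solution)
})

test_that("stratification bins follow the stated boundary conventions", {
  mk_call <- function(start) list(start_min_before_onset = start)
  expect_equal(stratify(mk_call(84)), "120-80")
  expect_equal(stratify(mk_call(130)), "unstratified")
  expect_equal(stratify(mk_call(40)), "40-0")
  expect_equal(stratify(mk_call(80)), "80-40")
  expect_equal(stratify(mk_call(120)), "120-80")
  expect_equal(stratify(mk_call(0)), "40-0")
})

test_that("every in-span start maps to exactly one bin", {
  for (s in seq(0, 120, by = 0.25)) {
    bin <- stratify(list(start_min_before_onset = s))
    expect_true(bin %in% c("120-80", "80-40", "40-0"))
  }
})

test_that("the SPH flag is inclusive at the horizon boundary", {
  expect_true(sph_flag(list(end_min_before_onset = 12), 10))
  expect_false(sph_flag(list(end_min_before_onset = 5), 10))
  expect_true(sph_flag(list(end_min_before_onset = 10), 10))
})

test_that("the independence filter keeps seizures separated by >= 240 min", {
  expect_identical(filter_independent_seizures(c(250, 350, 650)),
                   c(TRUE, FALSE, TRUE))
  expect_identical(filter_independent_seizures(300), TRUE)
  expect_identical(filter_independent_seizures(c(300, 540)), c(TRUE, TRUE))
  expect_identical(filter_independent_seizures(100), FALSE)
  expect_identical(filter_independent_seizures(100, require_lead_in = FALSE),
                   TRUE)
})

test_that("preictal calls carry span, bin and SPH information", {
  grid <- build_window_grid(240, 300, 5)
  # windows 1813..1872: starts 89..84.08 min before onset
  sol <- mk_sol(1813:1872)
  call <- preictal_call(sol, grid, seizure_id = "p1s1")
  expect_equal(call$start_min_before_onset, 240 - (1813 - 1) * 5 / 60)
  expect_equal(call$bin, "120-80")
  expect_equal(call$duration_min, duration_minutes(60, 5))
  expect_true(call$precedes_sph)
})

test_that("cohort summaries count coverage and prefer the bin nearest onset", {
  grid <- build_window_grid(240, 300, 5)
  calls <- list(
    preictal_call(mk_sol(1000:1039), grid, seizure_id = "s1"),
    preictal_call(mk_sol(2500:2539), grid, seizure_id = "s2"),
    preictal_call(mk_sol(1900:1939), grid, seizure_id = "s3"),
    NULL
  )
  rep <- cohort_summary(calls, n_seizures = 4)
  expect_equal(rep$overview$n_with_call, 3)
  expect_equal(rep$overview$coverage_pct, 75)

  # same seizure in two bins: the one nearer the seizure is tallied
  multi <- list(
    preictal_call(mk_sol(1900:1939), grid, seizure_id = "sX"),  # 120-80
    preictal_call(mk_sol(2700:2739), grid, seizure_id = "sX")   # 40-0
  )
  rep2 <- cohort_summary(multi, n_seizures = 1)
  expect_equal(rep2$overview$n_with_call, 1)
  got <- rep2$bins$n[rep2$bins$bin == "40-0"]
  expect_equal(got, 1)

  empty <- cohort_summary(list(NULL, NULL), n_seizures = 2)
  expect_equal(empty$overview$n_with_call, 0)
})
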
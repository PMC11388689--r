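# A small reference model built once for the file.
local_model <- local({
  co <- simulate_cohort(default_cohort_config(seed = 12))
  set.seed(71)
  build_reference_database(co, "24-2")
})

test_that("total deviation is zero on the predicted surface and linear", {
  m <- local_model
  age <- 55
  pred <- rep(0, m$pattern$n_points)
  pred[m$point_index] <- predict_reference(m, m$point_index, age)
  t0 <- make_test(pred)
  expect_equal(unname(total_deviation(t0, m, age)), rep(0, 52),
               tolerance = 1e-12)
  t2 <- make_test(pred + 2)
  expect_equal(unname(total_deviation(t2, m, age)), rep(2, 52),
               tolerance = 1e-12)
  t10 <- make_test(rep(30, 68), pattern_id = "10-2")
  expect_error(total_deviation(t10, m, age), "pattern mismatch")
  expect_error(total_deviation(make_test(1:10)$values, m, age), "malformed")
})

test_that("total deviation matches hand arithmetic on a 4-point toy", {
  m <- local_model
  age <- 60
  idx <- m$point_index[1:4]
  obs <- c(25, 30, 28, 33)
  expected <- obs - (m$intercept[idx] + m$slope[idx] * age)
  v <- rep(0, m$pattern$n_points)
  v[idx] <- obs
  td <- total_deviation(make_test(v), m, age)
  expect_equal(unname(td[1:4]), unname(expected))
})

test_that("general height is the k-th best TD value", {
  expect_equal(general_height(rep(3.5, 52)), 3.5)
  td <- c(rep(0, 51), -10)                    # 24-2: 8th best is 0
  expect_equal(general_height(td), 0)
  expect_equal(general_height(rep(0, 68)), 0) # 10-2 k = 11
  expect_error(general_height(1:5, k = 8), "too few points")
  set.seed(81)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    v <- rnorm(n)
    k <- ceiling(0.15 * n)
    expect_equal(general_height(v), sort(v, decreasing = TRUE)[k])
    expect_equal(general_height(v), -sort(-v)[k])  # brute-force oracle
  }
})

test_that("pattern deviation is shift-invariant", {
  set.seed(82)
  td <- rnorm(52)
  gh <- general_height(td)
  pd <- pattern_deviation(td, gh)
  td_shift <- td - 3
  pd_shift <- pattern_deviation(td_shift, general_height(td_shift))
  expect_equal(pd_shift, pd, tolerance = 1e-12)
  expect_equal(pattern_deviation(rep(0, 52), 0), rep(0, 52))
})

test_that("MD and PSD follow the variance-weighted definitions", {
  toy <- list(s2 = c(1, 4))
  expect_equal(mean_deviation(c(-2, 1), toy), -1.4)
  expect_equal(mean_deviation(rep(0, 2), toy), 0)
  expect_equal(mean_deviation(rep(-3, 2), toy), -3)   # weights cancel
  # 2-point toy by hand: mean(s2) = 2.5, MD = -1.4
  # PSD^2 = 2.5 * ((-2+1.4)^2/1 + (1+1.4)^2/4) / 1 = 2.5 * (0.36 + 1.44)
  expect_equal(pattern_sd(c(-2, 1), -1.4, toy), sqrt(2.5 * 1.8))
  expect_equal(pattern_sd(rep(-3, 5), -3, list(s2 = 1:5)), 0)
  # equal variances collapse to the sample SD of TD
  set.seed(83)
  td <- rnorm(52)
  eq <- list(s2 = rep(2.7, 52))
  expect_equal(pattern_sd(td, mean(td), eq), sd(td))
  expect_equal(mean_deviation(td, eq), mean(td))
})

test_that("classification is inclusive at limits and monotone", {
  lim <- c("5" = -4, "2" = -5, "1" = -6, "0.5" = -8)
  expect_equal(as.character(classify_value(-3.9, lim)), "ns")
  expect_equal(as.character(classify_value(-6, lim)), "p1")    # at the limit
  expect_equal(as.character(classify_value(-9, lim)), "p05")
  # sweep: categories non-increasing in the value
  sweep <- classify_value(seq(-10, 0, by = 0.1), lim)
  expect_true(all(diff(as.integer(sweep)) <= 0))
  # upper tail (PSD)
  ulim <- c("5" = 2.5, "2" = 3, "1" = 3.5, "0.5" = 4)
  expect_equal(as.character(classify_value(2.4, ulim, tail = "upper")), "ns")
  expect_equal(as.character(classify_value(3, ulim, tail = "upper")), "p2")
  expect_error(classify_value(0, c("5" = -4, "2" = -3, "1" = -6, "0.5" = -8)),
               "not monotone")
})

test_that("analyze_test satisfies the deviation identities", {
  m <- local_model
  co <- simulate_cohort(default_cohort_config(seed = 13))
  st <- co$tests[!co$tests$is_practice & co$tests$pattern_id == "24-2", ]
  for (i in c(1L, 5L)) {
    tst <- test_record(st, i)
    age <- co$subjects$age[co$subjects$subject_id == tst$subject_id]
    r <- analyze_test(tst, m, age)
    expect_equal(r$pd, r$td - r$gh, tolerance = 1e-12)
    expect_gte(r$psd, 0)
    expect_equal(r$md, mean_deviation(r$td, m))
    expect_length(r$prob_td, 52)
    expect_s3_class(r$prob_md, "factor")
  }
  # OS records are mirrored before analysis: same subject, same indices'
  # multiset under a left-right symmetric summary
  os <- test_record(st[st$eye == "OS", ], 1L)
  age <- co$subjects$age[co$subjects$subject_id == os$subject_id]
  r_os <- analyze_test(os, m, age)
  r_can <- analyze_test(mirror_to_canonical(os), m, age)
  expect_equal(r_os$md, r_can$md)
  expect_equal(r_os$td, r_can$td)
})

test_that("the median test has zero MD and PSD", {
  m <- local_model
  pred <- rep(0, m$pattern$n_points)
  pred[m$point_index] <- predict_reference(m, m$point_index, 50)
  r <- analyze_test(make_test(pred,
                              foveal_db = m$foveal$intercept +
                                m$foveal$slope * 50), m, 50)
  expect_equal(r$md, 0, tolerance = 1e-10)
  expect_equal(r$psd, 0, tolerance = 1e-10)
  expect_equal(r$foveal_dev, 0, tolerance = 1e-10)
  expect_true(all(r$prob_td == "ns"))
})

test_that("deviation results print and export", {
  m <- local_model
  pred <- rep(30, m$pattern$n_points)
  r <- analyze_test(make_test(pred), m, 50)
  out <- capture.output(print(r))
  expect_true(any(grepl("MD", out)))
  expect_true(any(grepl("total deviation", out)))
  f <- tempfile(fileext = ".json")
  write_deviation(r, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$md, r$md, tolerance = 1e-9)
  expect_equal(length(back$prob_td), 52)
})
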
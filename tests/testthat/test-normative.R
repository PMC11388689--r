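test_that("pointwise regression matches hand-computed OLS on a 3-subject toy", {
  p <- build_pattern("24-2")
  # every point: ages 30/50/70 with values 30/28/26 -> slope -0.1
  values <- matrix(rep(c(30, 28, 26), p$n_points), nrow = 3)
  fit <- fit_pointwise_regression(values, c(30, 50, 70), p)
  expect_equal(unname(fit$slope[p$analyzed]), rep(-0.1, 52), tolerance = 1e-12)
  expect_equal(unname(fit$intercept[p$analyzed]), rep(33, 52), tolerance = 1e-12)
  expect_true(all(is.na(fit$slope[-p$analyzed])))
  expect_equal(colMeans(fit$residuals), rep(0, 52), tolerance = 1e-9)
  expect_error(fit_pointwise_regression(values[1:2, ], c(30, 50), p),
               "insufficient data")
})

test_that("noise-free cohorts recover the truth slopes exactly", {
  cfg <- noiseless_config(seed = 4)
  co <- simulate_cohort(cfg)
  inc <- apply_exclusions(co)$included
  for (pid in VF_PATTERNS) {
    sv <- study_values_matrix(inc, pid)
    fit <- fit_pointwise_regression(sv$values, sv$age, pid)
    tr <- cfg$truth[[pid]]
    an <- build_pattern(pid)$analyzed
    expect_equal(unname(fit$slope[an]), -tr$slope_map[an], tolerance = 1e-8)
  }
})

test_that("reference prediction is linear in age and guards extrapolation", {
  co <- simulate_cohort(tiny_config(seed = 5))
  sv <- study_values_matrix(apply_exclusions(co)$included, "24-2")
  fit <- fit_pointwise_regression(sv$values, sv$age, "24-2")
  an <- fit$point_index
  d <- predict_reference(fit, an, 50) - predict_reference(fit, an, 80)
  expect_equal(d, -30 * fit$slope[an])
  expect_warning(v <- predict_reference(fit, an[1], 0), "extrapolating")
  expect_equal(v, fit$intercept[an[1]])
  expect_silent(predict_reference(fit, an[1], 60))
})

test_that("Hazen quantile equals the brute-force oracle", {
  expect_equal(nonparametric_quantile(1:100, 50), 50.5)
  expect_equal(nonparametric_quantile(7, 1), 7)
  expect_equal(nonparametric_quantile(7, 99), 7)
  expect_error(nonparametric_quantile(numeric(0), 50), "empty")
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    x <- round(rnorm(n, 0, 10), sample(0:3, 1))   # include ties
    lv <- runif(1, 0.1, 99.9)
    expect_equal(nonparametric_quantile(x, lv), hazen_oracle(x, lv))
  }
})

test_that("the reference database has ordered limits and eccentricity structure", {
  co <- simulate_cohort(default_cohort_config(seed = 1))
  set.seed(61)
  m <- build_reference_database(co, "24-2")
  expect_equal(m$n, 356L)
  expect_equal(m$gh_k, 8L)
  # quantile tables monotone in level at every point
  expect_true(all(apply(m$resid_q, 2, function(q) all(diff(q) >= 0))))
  expect_true(all(apply(m$pd_q, 2, function(q) all(diff(q) >= 0))))
  expect_true(all(m$s2 > 0))
  # global limits ordered: 0.5% <= 1% <= 2% <= 5% (lower tail), reversed PSD
  expect_true(!is.unsorted(m$md_limits[c("0.5", "1", "2", "5")]))
  expect_true(!is.unsorted(rev(m$psd_limits[c("0.5", "1", "2", "5")])))
  expect_true(!is.unsorted(m$foveal$limits[c("0.5", "1", "2", "5")]))
  # intersubject spread grows with eccentricity: 5% residual limit more
  # negative at the most eccentric analyzed point than at the least
  ecc <- eccentricity(m$pattern)[m$point_index]
  l5 <- m$resid_q["5", ]
  expect_lt(l5[which.max(ecc)], l5[which.min(ecc)])
  expect_gt(m$s2[which.max(ecc)], m$s2[which.min(ecc)])
  # left-skewed noise: lower extreme tail farther from zero than upper,
  # in aggregate over points
  expect_gt(mean(abs(m$resid_q["0.5", ])), mean(m$resid_q["99.5", ]))
})

test_that("a noise-free cohort yields zero limits and floored variances", {
  co <- simulate_cohort(noiseless_config(seed = 6))
  set.seed(62)
  m <- build_reference_database(co, "24-2")
  expect_equal(max(abs(m$resid_q)), 0, tolerance = 1e-7)
  expect_equal(unname(m$s2), rep(0.01, 52))
  expect_equal(unname(m$md_limits), rep(0, 4), tolerance = 1e-7)
})

test_that("pooling mirrored eyes leaves limits unchanged for symmetric truth", {
  # the 10-2 truth maps depend on x only through |x| within each hemifield
  # rule, so OD and OS study selections differ only by frame
  co <- simulate_cohort(noiseless_config(seed = 7))
  inc <- apply_exclusions(co)$included
  ids <- inc$subjects$subject_id
  set.seed(63)
  m_od <- build_reference_database(co, "10-2",
                                   setNames(rep("OD", length(ids)), ids))
  m_os <- build_reference_database(co, "10-2",
                                   setNames(rep("OS", length(ids)), ids))
  expect_equal(m_od$resid_q, m_os$resid_q, tolerance = 1e-8)
  expect_equal(m_od$slope, m_os$slope, tolerance = 1e-8)
})

test_that("mean fitted slope is recovered across seeds", {
  # cross-sectional recovery of the calibrated mean decline at n = 356
  rec <- vapply(1:20, function(s) {
    co <- simulate_cohort(default_cohort_config(seed = s))
    sv <- study_values_matrix(apply_exclusions(co)$included, "24-2")
    fit <- fit_pointwise_regression(sv$values, sv$age, "24-2")
    mean(-fit$slope, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(abs(rec - 0.06) < 0.01))
  expect_lt(abs(mean(rec) - 0.06), 0.003)
})

test_that("model JSON round-trips and the loader validates invariants", {
  co <- simulate_cohort(tiny_config(seed = 8))
  set.seed(64)
  m <- build_reference_database(co, "10-2")
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$slope, m$slope, tolerance = 1e-12)
  expect_equal(m2$resid_q, m$resid_q, tolerance = 1e-12)
  expect_equal(m2$md_limits, m$md_limits, tolerance = 1e-12)
  expect_equal(m2$s2, unname(m$s2), tolerance = 1e-12)
  expect_equal(m2$pattern$points, m$pattern$points)
  # corrupt the stored table -> integrity error on read
  bad <- m
  bad$resid_q["0.5", 1] <- bad$resid_q["5", 1] + 1
  write_model(bad, f)
  expect_error(read_model(f), "not monotone")
})
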
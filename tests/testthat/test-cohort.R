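test_that("demographics honour the age-bin design", {
  set.seed(1)
  cfg <- default_cohort_config()
  subj <- sample_demographics(cfg)
  expect_equal(nrow(subj), 356L)
  expect_equal(sum(subj$age >= 60 & subj$age <= 69), 62L)
  expect_equal(sum(subj$age >= 22 & subj$age <= 29), 59L)
  expect_true(all(subj$age >= 22 & subj$age <= 89))
  expect_true(all(subj$exclusion_reason == "none"))
  # eligibility fields drawn inside the eligible ranges
  ok <- vapply(seq_len(nrow(subj)), function(i) {
    check_eligibility(subj[i, ])$pass
  }, logical(1))
  expect_true(all(ok))

  cfg0 <- default_cohort_config(age_bins = default_age_bins(rep(0L, 7)))
  expect_equal(nrow(sample_demographics(cfg0)), 0L)
  cfg_bad <- cfg
  cfg_bad$age_bins$count[1] <- -1L
  expect_error(sample_demographics(cfg_bad), "negative")
})

test_that("mean age across seeds matches the uniform-within-bin design", {
  means <- vapply(1:10, function(s) {
    set.seed(s)
    mean(sample_demographics(default_cohort_config())$age)
  }, numeric(1))
  # design expectation 51.91; published cohort mean 52.3
  expect_lt(abs(mean(means) - 52.3), 1.0)
})

test_that("slope maps are calibrated exactly", {
  t24 <- default_norm_truth("24-2")
  t10 <- default_norm_truth("10-2")
  an24 <- build_pattern("24-2")$analyzed
  expect_equal(mean(t24$slope_map[an24]), 0.06, tolerance = 1e-12)
  expect_equal(sqrt(mean((t24$slope_map[an24] - 0.06)^2)), 0.01,
               tolerance = 1e-12)
  expect_equal(30 * max(t24$slope_map[an24]), 2.5, tolerance = 1e-12)
  expect_equal(mean(t10$slope_map), 0.05, tolerance = 1e-12)
  expect_equal(sqrt(mean((t10$slope_map - 0.05)^2)), 0.01, tolerance = 1e-12)
  expect_true(all(t24$slope_map > 0), all(t10$slope_map > 0))
})

test_that("noise SD increases with eccentricity and is positive", {
  for (pid in VF_PATTERNS) {
    tr <- default_norm_truth(pid)
    ecc <- eccentricity(build_pattern(pid))
    expect_true(all(tr$sigma_map > 0))
    expect_true(all(diff(tr$sigma_map[order(ecc)]) >= 0))
  }
})

test_that("true thresholds are linear in age", {
  tr <- default_norm_truth("24-2")
  expect_equal(true_threshold(tr, seq_along(tr$base_map), tr$A_ref),
               tr$base_map)
  d <- true_threshold(tr, 1:54, 50) - true_threshold(tr, 1:54, 80)
  expect_equal(d, 30 * tr$slope_map)
})

test_that("noise-free simulation reproduces the truth surface", {
  cfg <- noiseless_config()
  tr <- cfg$truth[["24-2"]]
  subj <- list(subject_id = "S1", age = 47L)
  set.seed(5)
  t1 <- simulate_test(subj, tr)
  expect_equal(t1$values, true_threshold(tr, 1:54, 47))
  expect_equal(t1$foveal_db,
               tr$foveal_base - tr$foveal_slope * (47 - tr$A_ref))
})

test_that("skewed noise has mean zero, unit variance and a left tail", {
  set.seed(7)
  x <- vfnorm:::rskew(1e5, 0.35)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1), 0.02)
  expect_lt(mean(x^3), -0.1)                 # negative skew
  # lower 0.5th percentile farther from zero than the upper 99.5th
  expect_gt(abs(quantile(x, 0.005)), abs(quantile(x, 0.995)))
  y <- vfnorm:::rskew(1e5, 0)
  expect_lt(abs(mean(y^3)), 0.05)            # symmetric when gamma = 0
})

test_that("simulated cohorts are deterministic and correctly structured", {
  cfg <- tiny_config(seed = 9)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$tests, co2$tests)

  n_inc <- sum(co1$subjects$exclusion_reason == "none")
  expect_equal(n_inc, 50L)
  expect_equal(nrow(co1$subjects), 50L + 20L)
  expect_equal(sum(!co1$subjects$binocular_capable), 15L)
  # 2 patterns x 2 eyes x (practice + study) per included subject
  expect_equal(nrow(co1$tests), n_inc * 8L)
  expect_true(all(table(co1$tests$is_practice) == n_inc * 4L))
  # excluded subjects carry no tests
  exc <- co1$subjects$subject_id[co1$subjects$exclusion_reason != "none"]
  expect_false(any(co1$tests$subject_id %in% exc))
  # final study tests pass the reliability gate (retest loop)
  st <- co1$tests[!co1$tests$is_practice, ]
  expect_true(all(pmax(st$fl_rate, st$fp_rate, st$fn_rate) <= 0.25 |
                    st$unreliable))
  expect_true(all(st$attempt >= 1L & st$attempt <= cfg$max_attempts))
  # values clipped to [0, 40], rates to [0, 1]
  v <- as.matrix(co1$tests[co1$tests$pattern_id == "24-2", sprintf("v%02d", 1:54)])
  expect_true(all(v >= 0 & v <= 40))
  expect_true(all(st$fl_rate >= 0 & st$fl_rate <= 1))
})

test_that("cohort mean sensitivity reproduces the calibration targets", {
  co <- simulate_cohort(default_cohort_config(seed = 3))
  inc <- apply_exclusions(co)$included
  for (pid in VF_PATTERNS) {
    p <- build_pattern(pid)
    sv <- study_values_matrix(inc, pid)
    ms <- rowMeans(sv$values[, p$analyzed])
    target <- if (pid == "24-2") 29.1 else 32.4
    expect_lt(abs(mean(ms) - target), 0.3)
  }
})

test_that("study_values_matrix mirrors OS eyes into the canonical frame", {
  co <- simulate_cohort(noiseless_config(seed = 2))
  inc <- apply_exclusions(co)$included
  ids <- inc$subjects$subject_id
  od <- study_values_matrix(inc, "24-2",
                            setNames(rep("OD", length(ids)), ids))
  os <- study_values_matrix(inc, "24-2",
                            setNames(rep("OS", length(ids)), ids))
  # noise-free: both eyes equal the canonical truth surface exactly
  expect_equal(od$values, os$values)
})
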
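## Synthetic normative cohort generator.
##
## The generator emulates the statistical structure a perimetric normative
## study assumes: a cohort with a prescribed age-bin design, an age-declining
## hill of vision, a subject-level general-height offset shared across points
## and eyes, and eccentricity-dependent, left-skewed pointwise noise.  Default
## calibration constants reproduce the published cohort summaries (mean
## sensitivity 29.1 dB on 24-2 / 32.4 dB on 10-2, foveal thresholds 34.1 /
## 34.0 dB, mean age decline 0.06 / 0.05 dB per year with across-point SD
## 0.01, maximum 30-year 24-2 decline of 2.5 dB).

EXCLUSION_REASONS <- c("ocular_condition", "re_outside_range",
                       "eye_not_eligible_committee", "incomplete",
                       "intolerant_imaging", "iop_ge_22")

#' Default age-bin design
#'
#' The seven-decade age-bin design of the normative study: bins 22-29, 30-39,
#' ..., 70-79 and 80-89 (the open-ended 80+ bin is sampled uniformly on
#' 80-89), with included counts 59/51/56/52/62/53/23 (total 356).
#'
#' @param counts Optional replacement counts (length 7).
#' @return Data frame with columns \code{lo}, \code{hi}, \code{count}.
#' @export
default_age_bins <- function(counts = c(59L, 51L, 56L, 52L, 62L, 53L, 23L)) {
  stopifnot(length(counts) == 7L, all(counts >= 0))
  data.frame(lo = c(22L, 30L, 40L, 50L, 60L, 70L, 80L),
             hi = c(29L, 39L, 49L, 59L, 69L, 79L, 89L),
             count = as.integer(counts))
}

## Population mean and variance of integer ages drawn uniformly within bins,
## with fixed per-bin counts (stratified design).
age_design_moments <- function(bins) {
  m <- (bins$lo + bins$hi) / 2
  v <- ((bins$hi - bins$lo + 1)^2 - 1) / 12
  total <- sum(bins$count)
  # an empty design (e.g. all-zero bins) contributes no age variance term
  if (total == 0) return(list(mean = mean(m), var = 0))
  w <- bins$count / total
  mu <- sum(w * m)
  list(mean = mu, var = sum(w * (v + m^2)) - mu^2)
}

## Standardize to population mean 0, SD 1.
pop_standardize <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Ground-truth normative surface for the synthetic generator
#'
#' Builds the per-point truth maps that \code{\link{simulate_test}} samples
#' from: a base sensitivity map at the reference age, a pointwise age-decline
#' map, an eccentricity-increasing noise-SD map, a skewness weight, and
#' foveal/duration parameters.
#'
#' The slope map is a smooth field (affine in eccentricity plus a
#' superior-hemifield increment) rescaled so that, over analyzed points, its
#' mean equals \code{mean_slope} and its population SD equals
#' \code{slope_sd} exactly; for the 24-2 the most steeply declining point is
#' pinned so that \code{30 * max(slope)} equals \code{max_decline_30yr}
#' exactly.  The noise-SD map \code{sigma0 + sigma1 * eccentricity} is
#' calibrated in closed form so that the analytic between-subject SD of mean
#' sensitivity (age term + general height + averaged pointwise noise)
#' reproduces \code{ms_sd}; the foveal residual SD is calibrated the same
#' way against \code{foveal_sd_total}.
#'
#' @param pattern_id \code{"24-2"} or \code{"10-2"}.
#' @param ms_mean,ms_sd Target cohort mean and between-subject SD of mean
#'   sensitivity (dB); defaults 29.1/1.3 (24-2) and 32.4/1.0 (10-2).
#' @param mean_slope,slope_sd Target mean and across-point SD of the age
#'   decline over analyzed points (dB/year); defaults 0.06/0.01 (24-2) and
#'   0.05/0.01 (10-2).
#' @param max_decline_30yr Maximum 30-year decline (dB), pinned exactly for
#'   the 24-2 (default 2.5); \code{NULL} disables pinning (10-2 default).
#' @param base_ecc_slope Decline of the base map with eccentricity
#'   (dB/degree, default 0.25): the hill of vision.
#' @param sigma0 Pointwise noise SD at fixation (dB).
#' @param gamma Skew blending weight in [0, 1): 0 gives symmetric Gaussian
#'   noise; larger values lengthen the lower (sensitivity-loss) tail.
#' @param gh_sd Between-subject general-height SD (dB), shared across points
#'   and eyes.
#' @param foveal_mean,foveal_sd_total Target cohort mean and total
#'   between-subject SD of the foveal threshold (dB).
#' @param A_ref Reference age (years) at which the base map is expressed
#'   (default 52.3, the cohort mean age).
#' @param age_bins Age-bin design used for the variance calibration.
#' @return An object of class \code{vf_truth} with elements
#'   \code{pattern_id}, \code{A_ref}, \code{base_map}, \code{slope_map},
#'   \code{sigma_map} (all length \code{n_points}), \code{gamma},
#'   \code{gh_sd}, \code{foveal_base}, \code{foveal_slope},
#'   \code{foveal_sd}, \code{duration_mean}, \code{duration_sd}.
#' @export
default_norm_truth <- function(pattern_id,
                               ms_mean = NULL, ms_sd = NULL,
                               mean_slope = NULL, slope_sd = 0.01,
                               max_decline_30yr = NULL,
                               base_ecc_slope = 0.25,
                               sigma0 = NULL, gamma = NULL, gh_sd = 0.3,
                               foveal_mean = NULL, foveal_sd_total = NULL,
                               A_ref = 52.3,
                               age_bins = default_age_bins()) {
  pattern <- build_pattern(pattern_id)
  is24 <- pattern_id == "24-2"
  if (is.null(ms_mean))    ms_mean    <- if (is24) 29.1 else 32.4
  if (is.null(ms_sd))      ms_sd      <- if (is24) 1.3  else 1.0
  if (is.null(mean_slope)) mean_slope <- if (is24) 0.06 else 0.05
  if (is.null(max_decline_30yr) && is24) max_decline_30yr <- 2.5
  if (is.null(sigma0))     sigma0     <- if (is24) 1.2  else 0.9
  if (is.null(gamma))      gamma      <- if (is24) 0.35 else 0.20
  if (is.null(foveal_mean))     foveal_mean     <- if (is24) 34.1 else 34.0
  if (is.null(foveal_sd_total)) foveal_sd_total <- if (is24) 4.3  else 4.7

  ecc <- eccentricity(pattern)
  an  <- pattern$analyzed
  n_an <- pattern$n_analyzed
  ## raw slope field: eccentricity trend + superior-hemifield increment
  raw <- ecc + 3 * (pattern$points$y > 0) * pattern$spacing / 6

  slope <- numeric(pattern$n_points)
  if (!is.null(max_decline_30yr)) {
    bstar <- max_decline_30yr / 30
    imax  <- an[which.max(raw[an])]
    rest  <- setdiff(an, imax)
    z     <- pop_standardize(raw[rest])
    a     <- (n_an * mean_slope - bstar) / (n_an - 1)
    b2    <- (n_an * slope_sd^2 - (bstar - mean_slope)^2 -
                (n_an - 1) * (a - mean_slope)^2) / (n_an - 1)
    if (b2 <= 0) stop("slope-map calibration infeasible for these targets")
    slope[rest] <- a + sqrt(b2) * z
    slope[imax] <- bstar
    if (max(slope[rest]) >= bstar) {
      stop("slope-map calibration: pinned maximum not unique")
    }
    slope[-an] <- a                       # blind-spot points: field baseline
  } else {
    z <- pop_standardize(raw[an])
    slope[an]  <- mean_slope + slope_sd * z
    slope[-an] <- mean_slope
  }
  if (any(slope <= 0)) stop("slope-map calibration produced non-positive decline")

  ## base map: hill of vision, mean over analyzed points pinned to ms_mean
  base <- ms_mean - base_ecc_slope * (ecc - mean(ecc[an]))

  ## sigma map: solve sigma1 so the analytic SD of MS matches ms_sd:
  ##   Var(MS) = mean_slope^2 * Var(age) + gh_sd^2 + sum(sigma_p^2)/N^2
  vage <- age_design_moments(age_bins)$var
  targ <- (ms_sd^2 - mean_slope^2 * vage - gh_sd^2) * n_an^2
  if (targ <= n_an * sigma0^2) {
    stop("sigma-map calibration infeasible: lower sigma0 or gh_sd")
  }
  e <- ecc[an]
  A <- sum(e^2); B <- 2 * sigma0 * sum(e); C <- n_an * sigma0^2 - targ
  sigma1 <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  sigma  <- sigma0 + sigma1 * ecc

  fv2 <- foveal_sd_total^2 - mean_slope^2 * vage - gh_sd^2
  if (fv2 <= 0) stop("foveal SD calibration infeasible")

  structure(list(
    pattern_id = pattern_id,
    A_ref      = A_ref,
    base_map   = base,
    slope_map  = slope,
    sigma_map  = sigma,
    sigma0     = sigma0,
    sigma1     = sigma1,
    gamma      = gamma,
    gh_sd      = gh_sd,
    foveal_base  = foveal_mean,
    foveal_slope = mean_slope,
    foveal_sd    = sqrt(fv2),
    duration_mean = if (is24) 3.18 else 3.58,
    duration_sd   = if (is24) 0.38 else 0.43
  ), class = "vf_truth")
}

#' Noise-free true threshold
#'
#' The deterministic age-corrected true sensitivity
#' \code{base - slope * (age - A_ref)} at one or more points.
#'
#' @param truth A \code{vf_truth}.
#' @param point_index Integer point indices (pattern order, 1-based).
#' @param age Age in years.
#' @return Threshold(s) in dB.
#' @export
true_threshold <- function(truth, point_index, age) {
  stopifnot(inherits(truth, "vf_truth"))
  truth$base_map[point_index] - truth$slope_map[point_index] * (age - truth$A_ref)
}

## Left-skewed unit-variance deviates: Z*(1-gamma) - gamma*(G-1) with
## G ~ Gamma(1,1), rescaled to variance 1.  gamma = 0 is standard normal.
rskew <- function(n, gamma) {
  raw <- stats::rnorm(n) * (1 - gamma) - gamma * (stats::rgamma(n, shape = 1) - 1)
  raw / sqrt((1 - gamma)^2 + gamma^2)
}

## Threshold value matrix for n subjects (rows) in the canonical frame.
simulate_values <- function(truth, ages, g, pattern) {
  n <- length(ages)
  np <- pattern$n_points
  mu <- outer(rep(1, n), truth$base_map) -
    outer(ages - truth$A_ref, truth$slope_map)
  eps <- matrix(rskew(n * np, truth$gamma), n, np) *
    outer(rep(1, n), truth$sigma_map)
  v <- mu + g + eps
  pmin(pmax(v, 0), 40)
}

default_reliability <- function() {
  list(fl = c(1, 30), fp = c(1, 40), fn = c(1, 40))
}

draw_rates <- function(n, reliability) {
  list(fl = stats::rbeta(n, reliability$fl[1], reliability$fl[2]),
       fp = stats::rbeta(n, reliability$fp[1], reliability$fp[2]),
       fn = stats::rbeta(n, reliability$fn[1], reliability$fn[2]))
}

#' Simulate a single visual-field test record
#'
#' Draws one eye's test from the truth model: pointwise values are
#' \code{true_threshold + g + eps} with \code{g} the subject-level
#' general-height offset and \code{eps} left-skewed noise with pointwise SD
#' \code{sigma_map}, clipped to [0, 40] dB; the foveal threshold is drawn
#' analogously from the foveal parameters; reliability rates come from Beta
#' distributions and the binocular test duration from a clipped normal.
#' Left-eye (OS) records are stored in the as-tested frame (see
#' \code{\link{mirror_to_canonical}}).
#'
#' @param subject One-row data frame (or list) with at least
#'   \code{subject_id} and \code{age}.
#' @param truth A \code{vf_truth}.
#' @param eye \code{"OD"} or \code{"OS"}.
#' @param g Subject general-height offset (dB); drawn from
#'   \code{N(0, gh_sd)} when \code{NULL}.
#' @param is_practice Practice-test flag.
#' @param attempt Attempt number (1-3).
#' @param reliability List of Beta parameters for the fl/fp/fn rates.
#' @return An object of class \code{vf_test}.
#' @export
simulate_test <- function(subject, truth, eye = "OD", g = NULL,
                          is_practice = FALSE, attempt = 1L,
                          reliability = default_reliability()) {
  stopifnot(inherits(truth, "vf_truth"), eye %in% c("OD", "OS"))
  pattern <- build_pattern(truth$pattern_id)
  if (is.null(g)) g <- stats::rnorm(1, 0, truth$gh_sd)
  vc <- drop(simulate_values(truth, subject$age, g, pattern))
  values <- if (eye == "OS") vc[mirror_permutation(pattern)] else vc
  foveal <- truth$foveal_base - truth$foveal_slope * (subject$age - truth$A_ref) +
    g + stats::rnorm(1, 0, truth$foveal_sd)
  foveal <- min(max(foveal, 0), 40)
  r <- draw_rates(1, reliability)
  structure(list(
    subject_id = subject$subject_id,
    eye        = eye,
    pattern_id = truth$pattern_id,
    values     = values,
    foveal_db  = foveal,
    fl_rate    = r$fl, fp_rate = r$fp, fn_rate = r$fn,
    duration_min = max(stats::rnorm(1, truth$duration_mean, truth$duration_sd), 0.5),
    attempt    = as.integer(attempt),
    is_practice = is_practice,
    frame      = "as-tested"
  ), class = "vf_test")
}

#' Default cohort configuration
#'
#' The study-condition configuration the generator ships with: the Table-style
#' age-bin design (356 included subjects), the published sex/race/ethnicity
#' proportions, the exclusion-reason counts (6/3/4/5/1/1, 376 enrolled), 15
#' monocular-only subjects, and the default calibrated truth maps for both
#' patterns.
#'
#' @param seed Integer seed controlling every random draw of
#'   \code{\link{simulate_cohort}}.
#' @param age_bins Age-bin design (see \code{\link{default_age_bins}}).
#' @param gamma_24,gamma_10 Skew weights passed to the truth maps (set both
#'   to 0 for a symmetric-noise cohort).
#' @return An object of class \code{vf_cohort_config}.
#' @export
default_cohort_config <- function(seed = 1L,
                                  age_bins = default_age_bins(),
                                  gamma_24 = 0.35, gamma_10 = 0.20) {
  structure(list(
    seed = as.integer(seed),
    age_bins = age_bins,
    sex_prop = c(male = 157, female = 199) / 356,
    race_prop = c(white = 240, black = 48, asian = 31,
                  native_american = 1, pacific_islander = 3,
                  multiracial = 17, other = 16) / 356,
    ethnicity_prop = c(hispanic = 52, not_hispanic = 304) / 356,
    truth = list(
      "24-2" = default_norm_truth("24-2", gamma = gamma_24, age_bins = age_bins),
      "10-2" = default_norm_truth("10-2", gamma = gamma_10, age_bins = age_bins)
    ),
    reliability = default_reliability(),
    n_excluded_by_reason = stats::setNames(c(6L, 3L, 4L, 5L, 1L, 1L),
                                           EXCLUSION_REASONS),
    monocular_only_count = 15L,
    max_attempts = 3L
  ), class = "vf_cohort_config")
}

#' Sample subject demographics
#'
#' Draws the included subjects of a synthetic cohort: integer ages uniform
#' within each configured age bin (exact per-bin counts), sex/race/ethnicity
#' from the configured proportions, and eligibility fields (acuity, IOP,
#' refraction) inside the eligible ranges.
#'
#' @param config A \code{vf_cohort_config}.
#' @param id_offset Starting offset for subject identifiers.
#' @return Data frame of \code{SubjectProfile} rows with
#'   \code{exclusion_reason = "none"} and \code{binocular_capable = TRUE}.
#' @export
sample_demographics <- function(config, id_offset = 0L) {
  stopifnot(inherits(config, "vf_cohort_config"))
  bins <- config$age_bins
  if (any(bins$count < 0)) stop("config error: negative age-bin count")
  n <- sum(bins$count)
  if (n == 0L) {
    return(subject_frame(n = 0L))
  }
  ages <- unlist(lapply(seq_len(nrow(bins)), function(i) {
    if (bins$count[i] == 0L) return(integer(0))
    sample(bins$lo[i]:bins$hi[i], bins$count[i], replace = TRUE)
  }))
  df <- subject_frame(n)
  df$subject_id <- sprintf("S%04d", id_offset + seq_len(n))
  df$age <- as.integer(ages)
  df$sex <- sample(names(config$sex_prop), n, TRUE, config$sex_prop)
  df$race <- sample(names(config$race_prop), n, TRUE, config$race_prop)
  df$ethnicity <- sample(names(config$ethnicity_prop), n, TRUE,
                         config$ethnicity_prop)
  df$va_logmar <- stats::runif(n, -0.1, log10(2))
  df$iop_od <- round(stats::runif(n, 10, 21), 1)
  df$iop_os <- round(stats::runif(n, 10, 21), 1)
  df$se_od  <- round(pmin(pmax(stats::rnorm(n, 0, 2), -6), 6), 2)
  df$se_os  <- round(pmin(pmax(stats::rnorm(n, 0, 2), -6), 6), 2)
  df$cyl_od <- round(-pmin(abs(stats::rnorm(n, 0, 0.75)), 2.5), 2)
  df$cyl_os <- round(-pmin(abs(stats::rnorm(n, 0, 0.75)), 2.5), 2)
  df
}

subject_frame <- function(n) {
  data.frame(
    subject_id = character(n), age = integer(n),
    sex = character(n), race = character(n), ethnicity = character(n),
    va_logmar = numeric(n),
    iop_od = numeric(n), iop_os = numeric(n),
    se_od = numeric(n), se_os = numeric(n),
    cyl_od = numeric(n), cyl_os = numeric(n),
    exclusion_reason = rep("none", n),
    binocular_capable = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

## Enrolled-but-excluded subjects; offending fields are made consistent with
## the recorded reason where the reason is field-based.
sample_excluded_subjects <- function(config, id_offset) {
  counts <- config$n_excluded_by_reason
  total <- sum(counts)
  if (total == 0L) return(subject_frame(0L))
  bins <- config$age_bins
  cfg2 <- config
  w <- if (sum(bins$count) > 0) bins$count else rep(1L, nrow(bins))
  picked <- sample(seq_len(nrow(bins)), total, TRUE, w)
  cfg2$age_bins$count <- as.integer(tabulate(picked, nbins = nrow(bins)))
  df <- sample_demographics(cfg2, id_offset = id_offset)
  df$exclusion_reason <- rep(names(counts), counts)
  bad_iop <- df$exclusion_reason == "iop_ge_22"
  df$iop_od[bad_iop] <- round(stats::runif(sum(bad_iop), 22, 28), 1)
  bad_re <- df$exclusion_reason == "re_outside_range"
  df$se_od[bad_re] <- round(stats::runif(sum(bad_re), 6.25, 9) *
                              sample(c(-1, 1), sum(bad_re), TRUE), 2)
  df
}

## Simulate study tests for both eyes with the reliability retest loop; the
## failed pair is re-run as a whole (binocular acquisition).  Returns a list
## of value matrices and metadata vectors for eyes OD/OS.
simulate_study_block <- function(subjects, truth, g, pattern, reliability,
                                 max_attempts) {
  n <- nrow(subjects)
  out <- list()
  for (eye in c("OD", "OS")) {
    out[[eye]] <- list(
      values = simulate_values(truth, subjects$age, g, pattern),
      rates  = draw_rates(n, reliability)
    )
  }
  attempt <- rep(1L, n)
  fails <- function() {
    f <- rep(FALSE, n)
    for (eye in c("OD", "OS")) {
      r <- out[[eye]]$rates
      f <- f | pmax(r$fl, r$fp, r$fn) > 0.25
    }
    f
  }
  bad <- fails()
  while (any(bad) && max(attempt[bad]) < max_attempts) {
    idx <- which(bad & attempt < max_attempts)
    for (eye in c("OD", "OS")) {
      out[[eye]]$values[idx, ] <-
        simulate_values(truth, subjects$age[idx], g[idx], pattern)
      r <- draw_rates(length(idx), reliability)
      out[[eye]]$rates$fl[idx] <- r$fl
      out[[eye]]$rates$fp[idx] <- r$fp
      out[[eye]]$rates$fn[idx] <- r$fn
    }
    attempt[idx] <- attempt[idx] + 1L
    bad <- fails()
  }
  out$attempt <- attempt
  out$unreliable <- bad
  out
}

#' Simulate a full synthetic normative cohort
#'
#' Generates the enrolled cohort a normative study screens and tests:
#' included subjects per the configured age-bin design, additional
#' enrolled-but-excluded subjects carrying exclusion-reason flags (no tests),
#' monocular-only flags, and — for every included subject — practice and
#' study 24-2 and 10-2 tests of both eyes.  Study tests pass through the
#' reliability retest loop (up to \code{max_attempts}); test order within
#' each practice/study pair is randomized per subject; the subject-level
#' general-height offset is shared across points, eyes and patterns.
#' Deterministic given \code{config$seed}.
#'
#' @param config A \code{vf_cohort_config}.
#' @return An object of class \code{vf_cohort}: list with \code{subjects}
#'   (data frame, included + excluded), \code{tests} (wide data frame, one
#'   row per eye per test; value columns \code{v01..v68}, NA-padded beyond
#'   the pattern's point count; OS rows stored in the as-tested frame),
#'   \code{patterns} and \code{config}.
#' @export
simulate_cohort <- function(config = default_cohort_config()) {
  stopifnot(inherits(config, "vf_cohort_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  subjects <- sample_demographics(config)
  n <- nrow(subjects)
  excluded <- sample_excluded_subjects(config, id_offset = n)
  if (config$monocular_only_count > n) {
    stop("config error: monocular_only_count exceeds included count")
  }
  if (n > 0L && config$monocular_only_count > 0L) {
    mono <- sample(n, config$monocular_only_count)
    subjects$binocular_capable[mono] <- FALSE
  }
  g <- stats::rnorm(n, 0, config$truth[["24-2"]]$gh_sd)
  ## randomized test order within the practice pair and the study pair
  ord_practice <- replicate(n, sample(VF_PATTERNS))
  ord_study    <- replicate(n, sample(VF_PATTERNS))

  rows <- list()
  for (pid in VF_PATTERNS) {
    pattern <- build_pattern(pid)
    truth <- config$truth[[pid]]
    if (n == 0L) next
    perm <- mirror_permutation(pattern)
    for (stage in c("practice", "study")) {
      if (stage == "practice") {
        blk <- list()
        for (eye in c("OD", "OS")) {
          blk[[eye]] <- list(
            values = simulate_values(truth, subjects$age, g, pattern),
            rates  = draw_rates(n, config$reliability)
          )
        }
        blk$attempt <- rep(1L, n)
        blk$unreliable <- rep(FALSE, n)
      } else {
        blk <- simulate_study_block(subjects, truth, g, pattern,
                                    config$reliability, config$max_attempts)
      }
      duration <- pmax(stats::rnorm(n, truth$duration_mean, truth$duration_sd), 0.5)
      foveal <- list()
      for (eye in c("OD", "OS")) {
        fv <- truth$foveal_base -
          truth$foveal_slope * (subjects$age - truth$A_ref) +
          g + stats::rnorm(n, 0, truth$foveal_sd)
        foveal[[eye]] <- pmin(pmax(fv, 0), 40)
      }
      ordm <- if (stage == "practice") ord_practice else ord_study
      visit_base <- if (stage == "practice") 0L else 2L
      visit <- visit_base + ifelse(ordm[1, ] == pid, 1L, 2L)
      for (eye in c("OD", "OS")) {
        vals <- blk[[eye]]$values
        if (eye == "OS") vals <- vals[, perm, drop = FALSE]   # as-tested frame
        vm <- matrix(NA_real_, n, 68)
        vm[, seq_len(pattern$n_points)] <- vals
        colnames(vm) <- sprintf("v%02d", 1:68)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects$subject_id,
          eye = eye, pattern_id = pid,
          is_practice = stage == "practice",
          attempt = blk$attempt,
          unreliable = blk$unreliable,
          visit_index = visit,
          foveal_db = foveal[[eye]],
          fl_rate = blk[[eye]]$rates$fl,
          fp_rate = blk[[eye]]$rates$fp,
          fn_rate = blk[[eye]]$rates$fn,
          duration_min = duration,
          vm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(
    subjects = rbind(subjects, excluded),
    tests = tests,
    patterns = lapply(stats::setNames(VF_PATTERNS, VF_PATTERNS), build_pattern),
    config = config
  ), class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  inc <- sum(x$subjects$exclusion_reason == "none")
  cat(sprintf("vf_cohort: %d subjects enrolled (%d included), %d test records\n",
              nrow(x$subjects), inc, if (is.null(x$tests)) 0L else nrow(x$tests)))
  invisible(x)
}

#' Extract one test row as a vf_test record
#'
#' @param tests Test data frame of a \code{vf_cohort} (or read back from CSV).
#' @param i Row index.
#' @return A \code{vf_test}.
#' @export
test_record <- function(tests, i) {
  row <- tests[i, , drop = FALSE]
  np <- build_pattern(row$pattern_id)$n_points
  structure(list(
    subject_id = row$subject_id,
    eye = row$eye,
    pattern_id = row$pattern_id,
    values = as.numeric(row[, sprintf("v%02d", seq_len(np))]),
    foveal_db = row$foveal_db,
    fl_rate = row$fl_rate, fp_rate = row$fp_rate, fn_rate = row$fn_rate,
    duration_min = row$duration_min,
    attempt = row$attempt,
    is_practice = row$is_practice,
    frame = "as-tested"
  ), class = "vf_test")
}

#' Canonical-frame study values for one pattern
#'
#' Pulls each included subject's final study test of the given eye, mirrors
#' left-eye records into the canonical frame, and returns the pointwise value
#' matrix alongside ages and foveal thresholds — the input to
#' \code{\link{fit_pointwise_regression}} and
#' \code{\link{build_reference_database}}.
#'
#' @param cohort A \code{vf_cohort} (included subjects only are used).
#' @param pattern_id Pattern identifier.
#' @param study_eyes Named character vector (subject_id -> "OD"/"OS"), e.g.
#'   from \code{\link{select_study_eye}}; defaults to "OD" for all.
#' @return List with \code{values} (subjects x points matrix, canonical
#'   frame), \code{foveal}, \code{age}, \code{subject_id}, \code{eye}.
#' @export
study_values_matrix <- function(cohort, pattern_id, study_eyes = NULL) {
  stopifnot(inherits(cohort, "vf_cohort"))
  pattern <- build_pattern(pattern_id)
  inc <- cohort$subjects[cohort$subjects$exclusion_reason == "none", ]
  tt <- cohort$tests
  tt <- tt[!tt$is_practice & tt$pattern_id == pattern_id &
             tt$subject_id %in% inc$subject_id, ]
  if (is.null(study_eyes)) {
    study_eyes <- stats::setNames(rep("OD", nrow(inc)), inc$subject_id)
  }
  keep <- tt$eye == study_eyes[tt$subject_id]
  tt <- tt[keep, ]
  tt <- tt[match(inc$subject_id, tt$subject_id), ]
  if (anyNA(tt$subject_id)) stop("missing study test for some included subject")
  vals <- as.matrix(tt[, sprintf("v%02d", seq_len(pattern$n_points))])
  perm <- mirror_permutation(pattern)
  os <- which(tt$eye == "OS")
  for (i in os) {
    vc <- numeric(pattern$n_points)
    vc[perm] <- vals[i, ]
    vals[i, ] <- vc
  }
  dimnames(vals) <- NULL
  list(values = vals, foveal = tt$foveal_db,
       age = inc$age[match(tt$subject_id, inc$subject_id)],
       subject_id = tt$subject_id, eye = tt$eye)
}
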
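## Reference-database construction: pointwise cross-sectional age regression,
## pooled age-corrected residual distributions, and nonparametric reference
## limits at the 5/2/1/0.5% levels for every analysis parameter.

## Quantile levels stored per point (%, lower and upper tails plus median).
MODEL_QLEVELS <- c(0.5, 1, 2, 5, 50, 95, 98, 99, 99.5)
LIMIT_LEVELS  <- c(5, 2, 1, 0.5)

#' Pointwise cross-sectional age regression
#'
#' Ordinary least squares of threshold sensitivity (dB) on age (years) at
#' every analyzed (non-blind-spot) test point, fitted cross-sectionally over
#' subjects.  All points are fitted in one multivariate \code{lm} call.
#'
#' @param values Numeric matrix, subjects x pattern points, canonical frame
#'   (see \code{\link{study_values_matrix}}).
#' @param age Numeric vector of subject ages (years).
#' @param pattern A \code{vf_pattern} (or pattern id string).
#' @return Object of class \code{vf_pointwise_fit}: \code{pattern_id};
#'   \code{intercept} and \code{slope} (length \code{n_points}, NA at
#'   blind-spot points, slope in dB/year, expected negative); \code{n};
#'   \code{point_index} (analyzed indices); \code{residuals} (subjects x
#'   analyzed-points matrix of age-corrected residuals, column mean 0).
#' @export
fit_pointwise_regression <- function(values, age, pattern) {
  if (is.character(pattern)) pattern <- build_pattern(pattern)
  stopifnot(inherits(pattern, "vf_pattern"),
            is.matrix(values), ncol(values) == pattern$n_points,
            nrow(values) == length(age))
  if (nrow(values) < 3L) {
    stop("insufficient data: pointwise regression needs >= 3 subjects, got ",
         nrow(values))
  }
  Y <- values[, pattern$analyzed, drop = FALSE]
  fit <- stats::lm(Y ~ age)
  co <- stats::coef(fit)                       # 2 x n_analyzed
  intercept <- slope <- rep(NA_real_, pattern$n_points)
  intercept[pattern$analyzed] <- co[1L, ]
  slope[pattern$analyzed]     <- co[2L, ]
  res <- stats::residuals(fit)
  dimnames(res) <- NULL
  structure(list(
    pattern_id  = pattern$pattern_id,
    point_index = pattern$analyzed,
    intercept   = intercept,
    slope       = slope,
    n           = nrow(values),
    residuals   = res
  ), class = "vf_pointwise_fit")
}

#' Age-corrected reference prediction
#'
#' The fitted age-corrected 50th-percentile surface:
#' \code{intercept + slope * age} at the requested points.  Ages outside the
#' guard range [22, 90] are extrapolations and trigger a warning (the value
#' is still returned).
#'
#' @param model A \code{vf_pointwise_fit} or \code{vf_norm_model}.
#' @param point_index Pattern point indices (1-based); default all points
#'   (NA at blind-spot points).
#' @param age Age in years (scalar).
#' @return Predicted thresholds in dB.
#' @export
predict_reference <- function(model, point_index = NULL, age) {
  stopifnot(inherits(model, c("vf_pointwise_fit", "vf_norm_model")))
  if (is.null(point_index)) point_index <- seq_along(model$intercept)
  if (age < 22 || age > 90) {
    warning("age ", age, " outside the reference range [22, 90]; extrapolating")
  }
  model$intercept[point_index] + model$slope[point_index] * age
}

#' Nonparametric quantile (Hazen rule)
#'
#' Order-statistic quantile with the Hazen plotting position
#' \code{(i - 0.5)/n} and linear interpolation between order statistics
#' (quantile type 5); the convention used for every reference limit in the
#' package.
#'
#' @param values Numeric vector (length >= 1).
#' @param level Level in percent, in (0, 100).
#' @return The quantile value.
#' @examples
#' nonparametric_quantile(1:100, 50)  # 50.5
#' @export
nonparametric_quantile <- function(values, level) {
  if (length(values) == 0L) stop("empty input to nonparametric_quantile")
  stopifnot(level > 0, level < 100)
  stats::quantile(values, level / 100, type = 5, names = FALSE)
}

## Hazen quantiles of each column, levels in percent -> levels x cols matrix.
col_quantiles <- function(mat, levels) {
  out <- apply(mat, 2L, stats::quantile, probs = levels / 100, type = 5,
               names = FALSE)
  matrix(out, nrow = length(levels),
         dimnames = list(as.character(levels), NULL))
}

#' Build a normative reference database
#'
#' The package's central constructor.  From one reliability-passed,
#' canonical-frame study test per included subject it (pass 1) fits the
#' pointwise age regressions and the foveal age regression, tabulates
#' per-point age-corrected residual quantiles (0.5/1/2/5/50/95/98/99/99.5%)
#' and residual variances, then (pass 2) computes every subject's deviation
#' indices against the fitted surfaces and tabulates per-point pattern
#' deviation quantiles and global reference limits for MD (lower tail), PSD
#' (upper tail) and foveal deviation (lower tail) at the 5/2/1/0.5% levels.
#' Deterministic given the cohort and eye selection.
#'
#' @param cohort A \code{vf_cohort}; exclusions and the reliability gate are
#'   applied, then one randomly selected eye per subject enters the database
#'   (supply \code{study_eyes} to fix the selection).
#' @param pattern_id \code{"24-2"} or \code{"10-2"}.
#' @param study_eyes Optional named vector (subject_id -> eye); when NULL a
#'   fair coin per subject is drawn from the current RNG state.
#' @param levels Reference-limit levels in percent (default 5/2/1/0.5).
#' @param gh_k General-height rank; default \code{ceiling(0.15 * n_analyzed)}.
#' @param var_floor Lower bound on the per-point residual variance (dB^2),
#'   keeping MD/PSD weights finite on degenerate inputs.
#' @return Object of class \code{vf_norm_model}; see
#'   \code{\link{write_model}} for the serialized schema.
#' @export
build_reference_database <- function(cohort, pattern_id, study_eyes = NULL,
                                     levels = LIMIT_LEVELS, gh_k = NULL,
                                     var_floor = 0.01) {
  stopifnot(inherits(cohort, "vf_cohort"))
  pattern <- build_pattern(pattern_id)
  cohort <- apply_exclusions(cohort)$included
  ## reliability gate: a subject whose final study test still fails in either
  ## eye cannot contribute
  tt <- cohort$tests[!cohort$tests$is_practice, ]
  bad <- unique(tt$subject_id[pmax(tt$fl_rate, tt$fp_rate, tt$fn_rate) > 0.25])
  if (length(bad)) {
    cohort$subjects <- cohort$subjects[!cohort$subjects$subject_id %in% bad, ]
    cohort$tests <- cohort$tests[!cohort$tests$subject_id %in% bad, ]
  }
  inc <- cohort$subjects
  if (is.null(study_eyes)) {
    study_eyes <- stats::setNames(
      ifelse(stats::runif(nrow(inc)) < 0.5, "OD", "OS"), inc$subject_id)
  }
  svm <- study_values_matrix(cohort, pattern_id, study_eyes)
  fit <- fit_pointwise_regression(svm$values, svm$age, pattern)

  resid_q <- col_quantiles(fit$residuals, MODEL_QLEVELS)
  n <- fit$n
  s2 <- pmax(colSums(fit$residuals^2) / (n - 2L), var_floor)

  ffit <- stats::lm(svm$foveal ~ svm$age)
  fres <- unname(stats::residuals(ffit))

  ## pass 2: per-subject indices against the fitted surfaces
  td <- fit$residuals
  if (is.null(gh_k)) gh_k <- as.integer(ceiling(0.15 * pattern$n_analyzed))
  gh <- apply(td, 1L, function(v) sort(v, decreasing = TRUE)[gh_k])
  pd <- td - gh
  w <- 1 / s2
  md <- as.numeric(td %*% w) / sum(w)
  N <- pattern$n_analyzed
  psd2 <- mean(s2) * as.numeric(((td - md)^2) %*% w) / (N - 1L)
  psd <- sqrt(pmax(psd2, 0))

  pd_q <- col_quantiles(pd, MODEL_QLEVELS)
  lv <- sort(levels, decreasing = TRUE)            # 5, 2, 1, 0.5
  md_limits  <- stats::setNames(vapply(lv, function(l)
    nonparametric_quantile(md, l), numeric(1)), as.character(lv))
  psd_limits <- stats::setNames(vapply(lv, function(l)
    nonparametric_quantile(psd, 100 - l), numeric(1)), as.character(lv))
  fov_limits <- stats::setNames(vapply(lv, function(l)
    nonparametric_quantile(fres, l), numeric(1)), as.character(lv))

  model <- structure(list(
    pattern_id  = pattern_id,
    pattern     = pattern,
    levels      = lv,
    qlevels     = MODEL_QLEVELS,
    point_index = fit$point_index,
    intercept   = fit$intercept,
    slope       = fit$slope,
    n           = n,
    resid_q     = resid_q,
    pd_q        = pd_q,
    s2          = s2,
    gh_k        = gh_k,
    md_limits   = md_limits,
    psd_limits  = psd_limits,
    foveal      = list(intercept = unname(stats::coef(ffit))[1L],
                       slope     = unname(stats::coef(ffit))[2L],
                       limits    = fov_limits),
    provenance  = list(n = n, build_date = format(Sys.Date()),
                       version = as.character(utils::packageVersion("vfnorm")))
  ), class = "vf_norm_model")
  validate_model(model)
  model
}

#' @export
print.vf_norm_model <- function(x, ...) {
  cat(sprintf("vf_norm_model %s: n = %d, %d analyzed points, levels %s%%\n",
              x$pattern_id, x$n, length(x$point_index),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

## Internal invariant checks, run on build and on read.
validate_model <- function(model) {
  stopifnot(inherits(model, "vf_norm_model"))
  if (any(model$s2 <= 0)) stop("model integrity: non-positive residual variance")
  mono <- apply(model$resid_q, 2L, function(q) all(diff(q) >= 0))
  if (!all(mono)) stop("model integrity: residual quantile table not monotone")
  mono_pd <- apply(model$pd_q, 2L, function(q) all(diff(q) >= 0))
  if (!all(mono_pd)) stop("model integrity: PD quantile table not monotone")
  if (is.unsorted(model$md_limits[as.character(sort(model$levels))])) {
    ## md limits ordered: 0.5% <= 1% <= 2% <= 5%
    stop("model integrity: MD limits not ordered")
  }
  ps <- model$psd_limits[as.character(sort(model$levels))]
  if (is.unsorted(rev(ps))) stop("model integrity: PSD limits not ordered")
  invisible(model)
}

## Lower-tail per-point limits (levels x points) for a parameter table.
point_limits <- function(qtab, levels, upper = FALSE) {
  lv <- if (upper) 100 - levels else levels
  qtab[as.character(lv), , drop = FALSE]
}
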
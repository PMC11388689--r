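## Sample-size determination by resampling: how often do the 95% CIs of the
## 0.5th/1st/2nd/5th percentile estimates stay disjoint at a candidate
## cohort size?

#' Replicate a reference dataset
#'
#' Concatenates k copies of the value vector (e.g. 263 values replicated 3
#' times give 789), exactly as the resampling procedure prescribes; the
#' empirical distribution is unchanged.
#'
#' @param values Numeric vector.
#' @param k Number of copies (>= 1).
#' @return Vector of length \code{k * length(values)}.
#' @export
replicate_dataset <- function(values, k) {
  stopifnot(k >= 1)
  rep(values, times = k)
}

#' Distribution-free confidence interval for a percentile
#'
#' Order-statistic CI for the \code{level}\% percentile: the ranks are the
#' Binomial(n, level/100) quantiles at \code{(1 - conf)/2} and
#' \code{(1 + conf)/2}, clamped to [1, n]; the CI is the pair of order
#' statistics at those ranks.  For samples smaller than 20 the full range is
#' returned with a warning (degenerate, very wide CI).
#'
#' @param sample Numeric vector (non-empty).
#' @param level Percentile level in percent.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector \code{c(lower, upper)}.
#' @examples
#' set.seed(1)
#' percentile_ci(rnorm(1000), 5)   # approx (x_(37), x_(64))
#' @export
percentile_ci <- function(sample, level, conf = 0.95) {
  n <- length(sample)
  if (n == 0L) stop("empty sample in percentile_ci")
  s <- sort(sample)
  if (n < 20L) {
    warning("sample size ", n, " < 20: returning the degenerate full-range CI")
    return(c(lower = s[1L], upper = s[n]))
  }
  p <- level / 100
  a <- (1 - conf) / 2
  l <- min(max(stats::qbinom(a, n, p), 1L), n)
  u <- min(max(stats::qbinom(1 - a, n, p), 1L), n)
  c(lower = s[l], upper = s[u])
}

## Strict disjointness of closed intervals.
ci_disjoint <- function(a, b) {
  a[["upper"]] < b[["lower"]] || b[["upper"]] < a[["lower"]]
}

#' Sample-size simulation for extreme-percentile reference limits
#'
#' Replicates the reference values \code{replicate_k} times, draws
#' \code{n_sim} simulated datasets of \code{n * values_per_n} values by
#' sampling with replacement, computes the distribution-free 95\% CI of each
#' requested percentile in every dataset, and reports the fraction of
#' datasets in which the CIs are pairwise disjoint — for adjacent percentile
#' pairs (0.5 vs 1, 1 vs 2, 2 vs 5) by default, or all pairs.
#'
#' \code{values_per_n} expresses how many reference values one subject
#' contributes: 1 for global parameters (MD, PSD), one per analyzed test
#' point for pointwise parameters (52 for 24-2 total/pattern deviation).
#'
#' @param reference Numeric vector of reference values (non-empty).
#' @param n Candidate number of subjects.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param percentiles Percentile levels in percent (default 0.5/1/2/5).
#' @param replicate_k Replication factor applied to the reference
#'   (default 3).
#' @param values_per_n Values contributed per subject (default 1).
#' @param mode \code{"adjacent"} (default) or \code{"allpairs"}.
#' @param conf CI confidence level.
#' @param seed Optional integer seed (determinism contract).
#' @return Object of class \code{vf_samplesize}: \code{n}, \code{n_sim},
#'   \code{percentiles}, \code{ci} (array n_sim x percentiles x 2),
#'   \code{nonoverlap_fraction}.
#' @export
run_sample_size_simulation <- function(reference, n, n_sim = 1000L,
                                       percentiles = c(0.5, 1, 2, 5),
                                       replicate_k = 3L, values_per_n = 1L,
                                       mode = c("adjacent", "allpairs"),
                                       conf = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (length(reference) == 0L) stop("empty reference")
  stopifnot(n >= 1, n_sim >= 1, values_per_n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pool <- replicate_dataset(reference, replicate_k)
  percentiles <- sort(percentiles)
  np <- length(percentiles)
  size <- as.integer(n) * as.integer(values_per_n)
  ci <- array(NA_real_, c(n_sim, np, 2L),
              dimnames = list(NULL, as.character(percentiles),
                              c("lower", "upper")))
  ok <- logical(n_sim)
  pairs <- if (mode == "adjacent") {
    cbind(seq_len(np - 1L), seq_len(np - 1L) + 1L)
  } else {
    t(utils::combn(np, 2L))
  }
  for (s in seq_len(n_sim)) {
    x <- sort(sample(pool, size, replace = TRUE))
    cis <- lapply(percentiles, function(l) {
      suppressWarnings(percentile_ci(x, l, conf))
    })
    for (j in seq_len(np)) ci[s, j, ] <- cis[[j]]
    ok[s] <- all(vapply(seq_len(nrow(pairs)), function(r) {
      ci_disjoint(cis[[pairs[r, 1L]]], cis[[pairs[r, 2L]]])
    }, logical(1)))
  }
  structure(list(
    n = as.integer(n), n_sim = as.integer(n_sim),
    values_per_n = as.integer(values_per_n),
    percentiles = percentiles, mode = mode,
    ci = ci,
    nonoverlap_fraction = mean(ok)
  ), class = "vf_samplesize")
}

#' @export
print.vf_samplesize <- function(x, ...) {
  cat(sprintf(
    "vf_samplesize: n = %d (%d values/subject), %d sims, %s pairs: nonoverlap fraction %.3f\n",
    x$n, x$values_per_n, x$n_sim, x$mode, x$nonoverlap_fraction))
  invisible(x)
}
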
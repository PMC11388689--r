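## Deviation indices for one test against a normative model: total
## deviation, general height, pattern deviation, MD, PSD, and probability
## classification.  MD/PSD follow the variance-weighted conventions standard
## in automated perimetry; the general height is the k-th best total
## deviation with k = ceiling(0.15 * N) (85th-percentile rank).

PROB_CATEGORIES <- c("ns", "p5", "p2", "p1", "p05")

#' Total deviation map
#'
#' Pointwise difference between observed thresholds and the age-corrected
#' reference prediction, at analyzed (non-blind-spot) points only.
#'
#' @param test A \code{vf_test} in the canonical frame (use
#'   \code{\link{mirror_to_canonical}} for OS records), or a numeric vector
#'   of pointwise values in canonical pattern order.
#' @param model A \code{vf_norm_model}.
#' @param age Subject age in years.
#' @return Numeric vector of TD values (dB), one per analyzed point.
#' @export
total_deviation <- function(test, model, age) {
  stopifnot(inherits(model, "vf_norm_model"))
  values <- if (inherits(test, "vf_test")) {
    if (test$pattern_id != model$pattern_id) {
      stop("pattern mismatch: test is ", test$pattern_id, ", model is ",
           model$pattern_id)
    }
    test$values
  } else {
    test
  }
  if (length(values) != model$pattern$n_points) {
    stop("malformed record: expected ", model$pattern$n_points, " values")
  }
  idx <- model$point_index
  values[idx] - (model$intercept[idx] + model$slope[idx] * age)
}

#' General height
#'
#' The k-th highest total-deviation value (k = \code{ceiling(0.15 * N)} by
#' default: 8 of 52 for the 24-2, 11 of 68 for the 10-2), estimating the
#' diffuse sensitivity offset of the test.
#'
#' @param td Numeric TD vector over analyzed points.
#' @param k Rank of the order statistic (from the top).
#' @return General height in dB.
#' @export
general_height <- function(td, k = NULL) {
  if (is.null(k)) k <- as.integer(ceiling(0.15 * length(td)))
  if (length(td) < k) {
    stop("too few points for general height: need ", k, ", got ", length(td))
  }
  sort(td, decreasing = TRUE)[k]
}

#' Pattern deviation map
#'
#' TD minus the general height: localizes focal loss after removing diffuse
#' offset.  Invariant under adding a constant to every TD value.
#'
#' @param td TD vector.
#' @param gh General height (dB).
#' @return PD vector (dB).
#' @export
pattern_deviation <- function(td, gh) {
  td - gh
}

#' Mean deviation
#'
#' Variance-weighted mean of the TD values:
#' \code{MD = sum(td/s2) / sum(1/s2)} over analyzed points, with \code{s2}
#' the per-point residual variances of the model.
#'
#' @param td TD vector over analyzed points.
#' @param model A \code{vf_norm_model}.
#' @return MD in dB.
#' @export
mean_deviation <- function(td, model) {
  w <- 1 / model$s2
  sum(td * w) / sum(w)
}

#' Pattern standard deviation
#'
#' Variance-weighted dispersion of TD about MD:
#' \code{PSD^2 = mean(s2) * sum((td - MD)^2 / s2) / (N - 1)};
#' \code{PSD = sqrt(max(PSD^2, 0))}.  With equal per-point variances this
#' collapses to the sample SD of the TD values.
#'
#' @param td TD vector over analyzed points (length >= 2).
#' @param md Mean deviation (dB).
#' @param model A \code{vf_norm_model}.
#' @return PSD in dB (>= 0).
#' @export
pattern_sd <- function(td, md, model) {
  N <- length(td)
  stopifnot(N >= 2L)
  psd2 <- mean(model$s2) * sum((td - md)^2 / model$s2) / (N - 1L)
  sqrt(max(psd2, 0))
}

#' Classify a value against monotone reference limits
#'
#' Returns the most extreme significance level whose limit the value
#' crosses.  Lower tail (TD, PD, MD, foveal deviation): smaller values are
#' abnormal.  Upper tail (PSD): larger values are abnormal.  A value exactly
#' at a limit classifies as flagged (inclusive).
#'
#' @param value Numeric scalar (or vector, classified elementwise).
#' @param limits Named numeric vector of limits, names the levels in percent
#'   ordered \code{"5","2","1","0.5"}.
#' @param tail \code{"lower"} or \code{"upper"}.
#' @return Factor with levels \code{ns < p5 < p2 < p1 < p05}.
#' @export
classify_value <- function(value, limits, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  lv <- as.numeric(names(limits))
  o <- order(lv, decreasing = TRUE)            # 5, 2, 1, 0.5
  limits <- limits[o]
  if (tail == "lower") {
    if (is.unsorted(rev(limits))) stop("model integrity: limits not monotone")
    cat_idx <- 1L + (outer(value, limits, "<=") %*% rep(1L, length(limits)))
  } else {
    if (is.unsorted(limits)) stop("model integrity: limits not monotone")
    cat_idx <- 1L + (outer(value, limits, ">=") %*% rep(1L, length(limits)))
  }
  factor(PROB_CATEGORIES[cat_idx], levels = PROB_CATEGORIES, ordered = TRUE)
}

## Per-point classification of a TD or PD map against a quantile table.
classify_map <- function(values, qtab, levels) {
  lim <- point_limits(qtab, levels)
  out <- vapply(seq_along(values), function(i) {
    as.character(classify_value(values[i],
                                stats::setNames(lim[, i], rownames(lim))))
  }, character(1))
  factor(out, levels = PROB_CATEGORIES, ordered = TRUE)
}

#' Analyze one test against a normative model
#'
#' Computes the full deviation result: TD and PD maps, general height, MD,
#' PSD, foveal deviation, and probability categories for every pointwise and
#' global parameter.  OS records are mirrored into the canonical frame
#' first.  TD/PD probability maps use lower-tail limits (depressed
#' sensitivity); PSD uses the upper tail.
#'
#' @param test A \code{vf_test}.
#' @param model A \code{vf_norm_model} of the same pattern.
#' @param age Subject age in years.
#' @return Object of class \code{vf_deviation} with elements \code{td},
#'   \code{pd}, \code{gh}, \code{md}, \code{psd}, \code{foveal_dev},
#'   \code{prob_td}, \code{prob_pd}, \code{prob_md}, \code{prob_psd},
#'   \code{prob_foveal}, \code{age}, \code{pattern_id}, \code{subject_id}.
#' @export
analyze_test <- function(test, model, age) {
  stopifnot(inherits(test, "vf_test"), inherits(model, "vf_norm_model"))
  if (test$eye == "OS" && !identical(test$frame, "canonical")) {
    test <- mirror_to_canonical(test, model$pattern)
  }
  td <- total_deviation(test, model, age)
  gh <- general_height(td, model$gh_k)
  pd <- pattern_deviation(td, gh)
  md <- mean_deviation(td, model)
  psd <- pattern_sd(td, md, model)
  fdev <- test$foveal_db - (model$foveal$intercept + model$foveal$slope * age)
  structure(list(
    subject_id = test$subject_id,
    pattern_id = model$pattern_id,
    age = age,
    td = td, pd = pd, gh = gh, md = md, psd = psd, foveal_dev = fdev,
    prob_td = classify_map(td, model$resid_q, model$levels),
    prob_pd = classify_map(pd, model$pd_q, model$levels),
    prob_md = classify_value(md, model$md_limits),
    prob_psd = classify_value(psd, model$psd_limits, tail = "upper"),
    prob_foveal = classify_value(fdev, model$foveal$limits)
  ), class = "vf_deviation")
}

## Spatial grid printout of a pointwise map (values or category glyphs).
format_grid <- function(pattern, values, fmt = "%6.1f", blank = "     .") {
  pts <- pattern$points
  full <- rep(NA_real_, pattern$n_points)
  full[pattern$analyzed] <- values
  ys <- sort(unique(pts$y), decreasing = TRUE)
  xs <- sort(unique(pts$x))
  lines <- character(0)
  for (y in ys) {
    cells <- vapply(xs, function(x) {
      i <- which(pts$x == x & pts$y == y)
      if (length(i) == 0L || is.na(full[i])) blank else sprintf(fmt, full[i])
    }, character(1))
    lines <- c(lines, paste(cells, collapse = ""))
  }
  lines
}

#' @export
print.vf_deviation <- function(x, ...) {
  pattern <- build_pattern(x$pattern_id)
  cat(sprintf("vf_deviation %s (age %g): MD %.2f dB [%s], PSD %.2f dB [%s], GH %.2f dB\n",
              x$pattern_id, x$age, x$md, as.character(x$prob_md),
              x$psd, as.character(x$prob_psd), x$gh))
  cat(sprintf("foveal deviation %.2f dB [%s]\n", x$foveal_dev,
              as.character(x$prob_foveal)))
  cat("total deviation (dB):\n")
  cat(format_grid(pattern, x$td), sep = "\n")
  cat("TD probability (. ns, 5/2/1 = p<.05/.02/.01, * = p<.005):\n")
  cat(glyph_grid(pattern, x$prob_td), sep = "\n")
  invisible(x)
}

glyph_grid <- function(pattern, categories) {
  glyph <- c(ns = " . ", p5 = " 5 ", p2 = " 2 ", p1 = " 1 ", p05 = " * ")
  pts <- pattern$points
  full <- rep(NA_character_, pattern$n_points)
  full[pattern$analyzed] <- glyph[as.character(categories)]
  ys <- sort(unique(pts$y), decreasing = TRUE)
  xs <- sort(unique(pts$x))
  vapply(ys, function(y) {
    paste(vapply(xs, function(x) {
      i <- which(pts$x == x & pts$y == y)
      if (length(i) == 0L || is.na(full[i])) "   " else full[i]
    }, character(1)), collapse = "")
  }, character(1))
}

#' Export a deviation result as JSON
#'
#' @param result A \code{vf_deviation}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_deviation <- function(result, path) {
  stopifnot(inherits(result, "vf_deviation"))
  obj <- result
  class(obj) <- NULL
  for (f in c("prob_td", "prob_pd", "prob_md", "prob_psd", "prob_foveal")) {
    obj[[f]] <- as.character(obj[[f]])
  }
  obj$format <- "vfnorm-deviation"
  obj$version <- as.character(utils::packageVersion("vfnorm"))
  obj$note <- paste("general-height rank and MD/PSD weights follow package",
                    "convention; device conventions are unpublished")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
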
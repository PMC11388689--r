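## File formats: cohort CSVs with a JSON sidecar, versioned model JSON,
## Snellen conversion.  CSV for tabular data, JSON for models and patterns;
## UTF-8 throughout; threshold columns must be complete (no missing values
## inside a pattern's point count).

#' Convert a Snellen acuity string to logMAR
#'
#' \code{"20/40"} gives \code{log10(40/20) = 0.301}; \code{"20/20"} gives 0.
#'
#' @param snellen Character vector like \code{"20/40"}.
#' @return Numeric logMAR values.
#' @export
snellen_to_logmar <- function(snellen) {
  parts <- regmatches(snellen, regexec("^\\s*(\\d+)\\s*/\\s*(\\d+)\\s*$", snellen))
  vapply(seq_along(snellen), function(i) {
    p <- parts[[i]]
    if (length(p) != 3L) stop("cannot parse Snellen acuity: '", snellen[i], "'")
    num <- as.numeric(p[2L]); den <- as.numeric(p[3L])
    if (num <= 0 || den <= 0) stop("cannot parse Snellen acuity: '", snellen[i], "'")
    log10(den / num)
  }, numeric(1))
}

test_columns <- function() {
  c("subject_id", "eye", "pattern_id", "is_practice", "attempt",
    "unreliable", "visit_index", "foveal_db", "fl_rate", "fp_rate",
    "fn_rate", "duration_min", sprintf("v%02d", 1:68))
}

#' Write / read test records as CSV
#'
#' One row per eye per test; pointwise values in wide columns
#' \code{v01..v68} (NA beyond the pattern's point count).  The schema is
#' validated on read with row-numbered errors; threshold columns inside the
#' pattern's point count must be complete.
#'
#' @param tests Test data frame (see \code{\link{simulate_cohort}}).
#' @param path CSV path.
#' @return \code{write_tests}: \code{path} invisibly; \code{read_tests}: the
#'   validated data frame.
#' @export
write_tests <- function(tests, path) {
  stopifnot(is.data.frame(tests))
  utils::write.csv(tests[, test_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tests
#' @export
read_tests <- function(path) {
  tests <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(test_columns(), names(tests))
  if (length(missing_cols)) {
    stop("tests file ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_pid <- which(!tests$pattern_id %in% VF_PATTERNS)
  if (length(bad_pid)) {
    stop("tests file row ", bad_pid[1L], ": unknown pattern_id '",
         tests$pattern_id[bad_pid[1L]], "'")
  }
  for (pid in unique(tests$pattern_id)) {
    np <- build_pattern(pid)$n_points
    rows <- which(tests$pattern_id == pid)
    vals <- as.matrix(tests[rows, sprintf("v%02d", seq_len(np))])
    if (anyNA(vals)) {
      i <- rows[which(rowSums(is.na(vals)) > 0)[1L]]
      stop("tests file row ", i, ": missing threshold values for pattern ", pid)
    }
  }
  rates <- as.matrix(tests[, c("fl_rate", "fp_rate", "fn_rate")])
  if (any(rates < 0 | rates > 1)) {
    i <- which(rowSums(rates < 0 | rates > 1) > 0)[1L]
    stop("tests file row ", i, ": reliability rates outside [0, 1]")
  }
  tests
}

#' Serialize / load a synthetic cohort
#'
#' Writes one subjects CSV, one tests CSV and a JSON sidecar holding the
#' seed, the calibrated truth parameters and the embedded pattern
#' definitions, so the directory is self-describing; the round trip is
#' lossless up to CSV numeric formatting (values are written with full
#' precision).
#'
#' @param cohort A \code{vf_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{write_cohort}: \code{dir} invisibly; \code{read_cohort}:
#'   the reconstructed \code{vf_cohort}.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  op <- options(digits = 17); on.exit(options(op))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_tests(cohort$tests, file.path(dir, "tests.csv"))
  cfg <- cohort$config
  sidecar <- list(
    format = "vfnorm-cohort",
    version = as.character(utils::packageVersion("vfnorm")),
    seed = cfg$seed,
    config = serialize_config(cfg),
    patterns = lapply(cohort$patterns, function(p) {
      list(pattern_id = p$pattern_id, spacing = p$spacing, points = p$points)
    })
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

serialize_config <- function(cfg) {
  out <- unclass(cfg)
  out$truth <- lapply(out$truth, unclass)
  out
}

deserialize_config <- function(obj) {
  cfg <- obj
  cfg$age_bins <- as.data.frame(cfg$age_bins)
  cfg$sex_prop <- unlist(cfg$sex_prop)
  cfg$race_prop <- unlist(cfg$race_prop)
  cfg$ethnicity_prop <- unlist(cfg$ethnicity_prop)
  cfg$reliability <- lapply(cfg$reliability, unlist)
  cfg$n_excluded_by_reason <- unlist(cfg$n_excluded_by_reason)
  cfg$truth <- lapply(cfg$truth, function(t) {
    t <- lapply(t, unlist)
    structure(t, class = "vf_truth")
  })
  structure(cfg, class = "vf_cohort_config")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  if (!identical(sidecar$format, "vfnorm-cohort")) {
    stop("not a vfnorm cohort directory: ", dir)
  }
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  tests <- read_tests(file.path(dir, "tests.csv"))
  structure(list(
    subjects = subjects,
    tests = tests,
    patterns = lapply(stats::setNames(VF_PATTERNS, VF_PATTERNS), build_pattern),
    config = deserialize_config(sidecar$config)
  ), class = "vf_cohort")
}

#' Serialize / load a normative model as versioned JSON
#'
#' All regression coefficients, quantile tables, variances, global limits
#' and provenance are embedded, together with the pattern definition; the
#' loader re-validates the model invariants (monotone quantile tables,
#' positive variances, ordered limits).
#'
#' @param model A \code{vf_norm_model}.
#' @param path JSON path.
#' @return \code{write_model}: \code{path} invisibly; \code{read_model}: the
#'   validated \code{vf_norm_model}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vf_norm_model"))
  obj <- unclass(model)
  obj$pattern <- list(pattern_id = model$pattern$pattern_id,
                      spacing = model$pattern$spacing,
                      points = model$pattern$points)
  obj$resid_q <- as.data.frame(t(model$resid_q))
  obj$pd_q <- as.data.frame(t(model$pd_q))
  # named atomic vectors lose their names in JSON arrays; store as objects
  obj$md_limits <- as.list(model$md_limits)
  obj$psd_limits <- as.list(model$psd_limits)
  obj$foveal$limits <- as.list(model$foveal$limits)
  obj$s2 <- unname(model$s2)
  obj$format <- "vfnorm-model"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vfnorm-model")) {
    stop("not a vfnorm model file: ", path)
  }
  pts <- as.data.frame(obj$pattern$points)
  pattern <- structure(list(
    pattern_id = obj$pattern$pattern_id,
    spacing = obj$pattern$spacing,
    points = data.frame(x = as.integer(pts$x), y = as.integer(pts$y),
                        is_blind_spot = as.logical(pts$is_blind_spot)),
    n_points = nrow(pts),
    analyzed = which(!pts$is_blind_spot),
    n_analyzed = sum(!pts$is_blind_spot)
  ), class = "vf_pattern")
  qn <- as.character(obj$qlevels)
  model <- structure(list(
    pattern_id = obj$pattern_id,
    pattern = pattern,
    levels = as.numeric(obj$levels),
    qlevels = as.numeric(obj$qlevels),
    point_index = as.integer(obj$point_index),
    intercept = as.numeric(obj$intercept),
    slope = as.numeric(obj$slope),
    n = as.integer(obj$n),
    resid_q = matrix(t(as.matrix(as.data.frame(obj$resid_q))),
                     nrow = length(qn), dimnames = list(qn, NULL)),
    pd_q = matrix(t(as.matrix(as.data.frame(obj$pd_q))),
                  nrow = length(qn), dimnames = list(qn, NULL)),
    s2 = as.numeric(obj$s2),
    gh_k = as.integer(obj$gh_k),
    md_limits = unlist(obj$md_limits),
    psd_limits = unlist(obj$psd_limits),
    foveal = list(intercept = obj$foveal$intercept,
                  slope = obj$foveal$slope,
                  limits = unlist(obj$foveal$limits)),
    provenance = obj$provenance
  ), class = "vf_norm_model")
  validate_model(model)
  model
}
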
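## Eligibility screening, reliability gating with retest, study-eye
## selection, and exclusion accounting.

## Boundary semantics, all inclusive of the printed bound:
##   age >= 22 passes; acuity 20/40 (logMAR log10(2)) passes; IOP <= 21
##   passes; |SE| <= 6 D passes; |cyl| <= 2.5 D passes.
VA_CUTOFF_LOGMAR <- log10(2)

#' Check subject eligibility
#'
#' Applies the enrollment rules: age >= 22 years, corrected acuity 20/40 or
#' better in logMAR, IOP <= 21 mmHg in both eyes, spherical equivalent not
#' exceeding +/-6 D, cylinder not exceeding +/-2.5 D.  Every violated rule is
#' reported; all bounds are inclusive (the printed limit passes).
#'
#' @param subject One-row data frame or list with fields \code{age},
#'   \code{va_logmar}, \code{iop_od}, \code{iop_os}, \code{se_od},
#'   \code{se_os}, \code{cyl_od}, \code{cyl_os}.
#' @return List with \code{pass} (logical) and \code{reasons} (character
#'   vector among \code{"age"}, \code{"acuity"}, \code{"iop"},
#'   \code{"refraction"}, \code{"cylinder"}).
#' @export
check_eligibility <- function(subject) {
  need <- c("age", "va_logmar", "iop_od", "iop_os",
            "se_od", "se_os", "cyl_od", "cyl_os")
  for (f in need) {
    v <- subject[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("missing eligibility field: ", f)
    }
  }
  eps <- 1e-9
  reasons <- character(0)
  if (subject$age < 22) reasons <- c(reasons, "age")
  if (subject$va_logmar > VA_CUTOFF_LOGMAR + eps) reasons <- c(reasons, "acuity")
  if (max(subject$iop_od, subject$iop_os) > 21 + eps) reasons <- c(reasons, "iop")
  if (max(abs(subject$se_od), abs(subject$se_os)) > 6 + eps) {
    reasons <- c(reasons, "refraction")
  }
  if (max(abs(subject$cyl_od), abs(subject$cyl_os)) > 2.5 + eps) {
    reasons <- c(reasons, "cylinder")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Check test reliability
#'
#' A test fails iff any of the fixation-loss, false-positive or
#' false-negative rates strictly exceeds 25\% (a rate of exactly 0.25
#' passes).  Monotone: raising any rate never converts a fail into a pass.
#'
#' @param test A \code{vf_test}, or a list/one-row data frame with
#'   \code{fl_rate}, \code{fp_rate}, \code{fn_rate} in [0, 1].
#' @return \code{TRUE} if reliable.
#' @export
check_reliability <- function(test) {
  r <- c(test$fl_rate, test$fp_rate, test$fn_rate)
  stopifnot(length(r) == 3L, all(r >= 0), all(r <= 1))
  max(r) <= 0.25
}

#' Re-run an unreliable test up to a maximum number of attempts
#'
#' Simulates (or, in live use, re-requests) a binocular test pair for one
#' subject until both eyes pass the reliability gate or \code{max_attempts}
#' is reached; the whole pair is re-run on failure (binocular acquisition).
#'
#' @param subject One-row subject data frame (needs \code{subject_id},
#'   \code{age}).
#' @param truth A \code{vf_truth} for the pattern being tested.
#' @param g Optional general-height offset to hold fixed across attempts.
#' @param max_attempts Maximum attempts (>= 1, default 3).
#' @param reliability Beta parameters for the simulated rates.
#' @return List with \code{tests} (list of \code{vf_test}, one per eye, from
#'   the final attempt), \code{attempt} (number used) and \code{reliable}
#'   (FALSE if every attempt failed, in which case the subject is excluded
#'   from the reference database).
#' @export
retest_until_reliable <- function(subject, truth, g = NULL, max_attempts = 3L,
                                  reliability = default_reliability()) {
  stopifnot(max_attempts >= 1L)
  if (is.null(g)) g <- stats::rnorm(1, 0, truth$gh_sd)
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    tests <- lapply(c("OD", "OS"), function(eye) {
      simulate_test(subject, truth, eye = eye, g = g, attempt = attempt,
                    reliability = reliability)
    })
    ok <- all(vapply(tests, check_reliability, logical(1)))
    if (ok || attempt >= max_attempts) {
      return(list(tests = tests, attempt = attempt, reliable = ok))
    }
  }
}

#' Randomly select the study eye
#'
#' One eye per subject enters the reference database.  A fair coin decides
#' when both eyes were tested; when only one eye is available (monocular
#' subjects with a single tested eye) that eye is returned deterministically.
#'
#' @param subject One-row subject data frame or list.
#' @param available Eyes with usable tests (default both).
#' @return \code{"OD"} or \code{"OS"}.
#' @export
select_study_eye <- function(subject, available = c("OD", "OS")) {
  available <- intersect(c("OD", "OS"), available)
  if (length(available) == 0L) stop("no tested eye available")
  if (length(available) == 1L) return(available)
  sample(c("OD", "OS"), 1L)
}

#' Apply exclusions and tally by reason
#'
#' Removes flagged subjects from an enrolled cohort and produces the
#' exclusion accounting: counts per reason, enrolled, excluded and included
#' totals.  Conservation holds exactly: enrolled = included + sum of reason
#' counts.
#'
#' @param cohort A \code{vf_cohort}, or a subjects data frame with an
#'   \code{exclusion_reason} column.
#' @return List with \code{included} (same type as input, excluded subjects
#'   and their rows removed) and \code{tally} (class \code{vf_tally}).
#' @export
apply_exclusions <- function(cohort) {
  subjects <- if (inherits(cohort, "vf_cohort")) cohort$subjects else cohort
  if (is.null(subjects$exclusion_reason) && nrow(subjects) > 0L) {
    stop("subjects lack an exclusion_reason column")
  }
  keep <- if (nrow(subjects) == 0L) logical(0) else subjects$exclusion_reason == "none"
  counts <- vapply(EXCLUSION_REASONS, function(r) {
    sum(subjects$exclusion_reason == r)
  }, integer(1))
  tally <- structure(list(
    counts = counts,
    n_enrolled = nrow(subjects),
    n_excluded = sum(!keep),
    n_included = sum(keep)
  ), class = "vf_tally")
  included <- if (inherits(cohort, "vf_cohort")) {
    out <- cohort
    out$subjects <- subjects[keep, , drop = FALSE]
    if (!is.null(out$tests)) {
      out$tests <- out$tests[out$tests$subject_id %in% out$subjects$subject_id, ,
                             drop = FALSE]
    }
    out
  } else {
    subjects[keep, , drop = FALSE]
  }
  list(included = included, tally = tally)
}

#' @export
print.vf_tally <- function(x, ...) {
  cat(sprintf("enrolled %d = included %d + excluded %d\n",
              x$n_enrolled, x$n_included, x$n_excluded))
  print(x$counts)
  invisible(x)
}

#' @rdname apply_exclusions
#' @param tally A \code{vf_tally}.
#' @param path Output CSV path.
#' @export
write_tally <- function(tally, path) {
  stopifnot(inherits(tally, "vf_tally"))
  df <- data.frame(reason = c(names(tally$counts), "excluded_total",
                              "included", "enrolled"),
                   count = c(unname(tally$counts), tally$n_excluded,
                             tally$n_included, tally$n_enrolled))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
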
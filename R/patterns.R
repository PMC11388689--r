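#' Supported perimetric test patterns
#'
#' Identifiers of the stimulus grids the package knows how to build:
#' the 54-point 24-2 grid (6 degree spacing, two blind-spot points) and the
#' 68-point 10-2 grid (2 degree spacing, no blind-spot points).
#'
#' @format Character vector of pattern identifiers.
#' @export
VF_PATTERNS <- c("24-2", "10-2")

#' Build a perimetric test-pattern geometry
#'
#' Constructs the full point grid for a named static-perimetry test pattern in
#' the canonical right-eye frame: x positive towards the nasal field, y
#' positive superior, coordinates in signed integer degrees of visual angle.
#'
#' Membership rules:
#' \itemize{
#'   \item \code{"24-2"}: both coordinates odd multiples of 3 with
#'     \code{|x| + |y| <= 30} and \code{|y| <= 21}, excluding the two temporal
#'     points at \code{(-27, +/-3)}; this yields the standard 54-point chart
#'     with row counts 4/6/8/9/9/8/6/4 and the two extra nasal points at
#'     \code{(27, +/-3)}.  The points at temporal 15 degrees, \code{y = +/-3}
#'     overlie the physiologic blind spot and are flagged (never removed);
#'     52 points are analyzed.
#'   \item \code{"10-2"}: both coordinates odd integers with
#'     \code{x^2 + y^2 <= 89}, giving 17 points per quadrant (68 total, all
#'     analyzed, all within 9 degrees of fixation).  The radial rule is a
#'     stand-in for the vendor layout; alternative layouts can be supplied via
#'     \code{\link{read_pattern}}.
#' }
#'
#' Point ordering is deterministic and row-major: superior to inferior
#' (decreasing y), then temporal to nasal (increasing x).
#'
#' @param pattern_id One of \code{"24-2"} or \code{"10-2"}.
#' @return An object of class \code{vf_pattern}: a list with elements
#'   \code{pattern_id}, \code{spacing} (degrees between neighbouring points),
#'   \code{points} (data frame with columns \code{x}, \code{y},
#'   \code{is_blind_spot}), \code{n_points}, \code{analyzed} (indices of
#'   non-blind-spot points) and \code{n_analyzed}.
#' @examples
#' p <- build_pattern("24-2")
#' p$n_points     # 54
#' p$n_analyzed   # 52
#' @export
build_pattern <- function(pattern_id) {
  if (length(pattern_id) != 1L || !pattern_id %in% VF_PATTERNS) {
    stop("unsupported pattern_id: ", paste(pattern_id, collapse = ", "),
         " (supported: ", paste(VF_PATTERNS, collapse = ", "), ")")
  }
  if (pattern_id == "24-2") {
    g <- expand.grid(x = seq(-27L, 27L, 6L), y = seq(-21L, 21L, 6L))
    g <- g[abs(g$x) + abs(g$y) <= 30L, , drop = FALSE]
    g <- g[g$x != -27L, , drop = FALSE]           # extra points are nasal only
    bs <- g$x == -15L & abs(g$y) == 3L            # temporal 15 deg, y = +/-3
    spacing <- 6
  } else {
    g <- expand.grid(x = seq(-9L, 9L, 2L), y = seq(-9L, 9L, 2L))
    g <- g[g$x^2 + g$y^2 <= 89L, , drop = FALSE]
    bs <- rep(FALSE, nrow(g))
    spacing <- 2
  }
  ord <- order(-g$y, g$x)
  pts <- data.frame(x = as.integer(g$x[ord]), y = as.integer(g$y[ord]),
                    is_blind_spot = bs[ord])
  structure(list(
    pattern_id = pattern_id,
    spacing    = spacing,
    points     = pts,
    n_points   = nrow(pts),
    analyzed   = which(!pts$is_blind_spot),
    n_analyzed = sum(!pts$is_blind_spot)
  ), class = "vf_pattern")
}

#' @export
print.vf_pattern <- function(x, ...) {
  cat(sprintf("vf_pattern %s: %d points (%d analyzed), spacing %g deg\n",
              x$pattern_id, x$n_points, x$n_analyzed, x$spacing))
  invisible(x)
}

#' Eccentricity of test points
#'
#' Euclidean radial distance from fixation, in degrees of visual angle.
#'
#' @param x A \code{vf_pattern}, or a numeric vector of x coordinates.
#' @param y Numeric vector of y coordinates (ignored when \code{x} is a
#'   pattern).
#' @return Numeric vector of eccentricities (>= 0), one per point.
#' @examples
#' eccentricity(3, 3)            # sqrt(18)
#' eccentricity(build_pattern("10-2"))
#' @export
eccentricity <- function(x, y = NULL) {
  if (inherits(x, "vf_pattern")) {
    return(sqrt(x$points$x^2 + x$points$y^2))
  }
  sqrt(x^2 + y^2)
}

## Permutation taking stored (mirrored-frame) values to canonical order:
## canonical point k at (x, y) was measured at (-x, y) in the stored frame,
## whose stored position is the rank of (-x, y) under the row-major ordering.
mirror_permutation <- function(pattern) {
  mx <- -pattern$points$x
  my <- pattern$points$y
  order(-my, mx)
}

#' Mirror a test record into the canonical right-eye frame
#'
#' The package pools randomly selected right and left eyes, so all analyses
#' are performed in a shared canonical frame (right-eye orientation, x
#' positive nasal).  Right-eye (OD) records are already canonical and are
#' returned unchanged.  Left-eye (OS) records have the nasal/temporal axis
#' negated: the value measured at \code{(x, y)} is re-indexed to
#' \code{(-x, y)} under the pattern's deterministic ordering.  The operation
#' is an involution: mirroring twice restores the original record.
#'
#' @param test A \code{vf_test} record (see \code{\link{simulate_test}}).
#' @param pattern Optional \code{vf_pattern}; defaults to
#'   \code{build_pattern(test$pattern_id)}.
#' @return The record with values in canonical order and
#'   \code{frame = "canonical"}; mirroring a canonical OS record restores the
#'   as-tested frame.
#' @export
mirror_to_canonical <- function(test, pattern = NULL) {
  stopifnot(inherits(test, "vf_test"))
  if (is.null(pattern)) pattern <- build_pattern(test$pattern_id)
  if (length(test$values) != pattern$n_points) {
    stop("malformed record: ", length(test$values), " values for pattern ",
         pattern$pattern_id, " (", pattern$n_points, " points)")
  }
  if (test$eye == "OD") return(test)
  perm <- mirror_permutation(pattern)
  out <- test
  out$values <- numeric(pattern$n_points)
  out$values[perm] <- test$values
  out$frame <- if (identical(test$frame, "canonical")) "as-tested" else "canonical"
  out
}

#' Export a test pattern as JSON
#'
#' Writes the pattern geometry (identifier, spacing and the ordered list of
#' \code{[x, y, is_blind_spot]} triples) so downstream files are
#' self-describing and alternative layouts can be swapped in.
#'
#' @param pattern A \code{vf_pattern}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "vf_pattern"))
  obj <- list(
    format      = "vfnorm-pattern",
    version     = as.character(utils::packageVersion("vfnorm")),
    pattern_id  = pattern$pattern_id,
    spacing     = pattern$spacing,
    points      = pattern$points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a test pattern from JSON
#'
#' Counterpart of \code{\link{write_pattern}}; validates the schema and
#' rebuilds the \code{vf_pattern} object (ordering is taken from the file).
#'
#' @param path JSON file written by \code{\link{write_pattern}} (or a
#'   hand-made file with the same schema, e.g. a vendor 10-2 layout).
#' @return A \code{vf_pattern}.
#' @export
read_pattern <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vfnorm-pattern")) {
    stop("not a vfnorm pattern file: ", path)
  }
  for (f in c("pattern_id", "spacing", "points")) {
    if (is.null(obj[[f]])) stop("pattern file missing field '", f, "': ", path)
  }
  pts <- as.data.frame(obj$points)
  structure(list(
    pattern_id = obj$pattern_id,
    spacing    = obj$spacing,
    points     = data.frame(x = as.integer(pts$x), y = as.integer(pts$y),
                            is_blind_spot = as.logical(pts$is_blind_spot)),
    n_points   = nrow(pts),
    analyzed   = which(!pts$is_blind_spot),
    n_analyzed = sum(!pts$is_blind_spot)
  ), class = "vf_pattern")
}
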
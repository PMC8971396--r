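#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All user-facing containers are plain
# data.frames or small classed lists; these helpers build and validate them.

#' Construct an association result
#'
#' Light-weight container for the output of a single statistical test:
#' the statistic, its null distribution's degrees of freedom, the p-value,
#' and (where defined) an odds ratio with a confidence interval.
#'
#' @param statistic_name One of `"chi2"`, `"fisher"`, `"wald"`, `"t"`,
#'   `"or_logistic"`, `"or_2x2"`.
#' @param statistic Test statistic (NA for exact tests with no statistic).
#' @param df Degrees of freedom or NA.
#' @param p Two-sided p-value.
#' @param or,ci_low,ci_high Odds ratio and confidence bounds, or NA.
#' @param note Optional character note (e.g. continuity corrections applied).
#' @return An object of class `assoc_result` (a named list).
#' @export
assoc_result <- function(statistic_name, statistic = NA_real_, df = NA_real_,
                         p = NA_real_, or = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, note = NULL) {
  stopifnot(is.character(statistic_name), length(statistic_name) == 1L)
  if (!is.na(p) && (p < 0 || p > 1)) stop("p-value outside [0, 1]")
  if (!is.na(or) && !is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= or && or <= ci_high)) {
    stop("confidence interval does not bracket the odds ratio")
  }
  structure(
    list(statistic_name = statistic_name, statistic = unname(statistic),
         df = unname(df), p = unname(p), or = unname(or),
         ci_low = unname(ci_low), ci_high = unname(ci_high), note = note),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, digits = 4, ...) {
  cat(sprintf("<%s>", x$statistic_name))
  if (!is.na(x$statistic)) cat(sprintf(" statistic = %.4g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(" (df = %g)", x$df))
  cat(sprintf(", p = %.3g", x$p))
  if (!is.na(x$or)) {
    cat(sprintf(", OR = %.3g", x$or))
    if (!is.na(x$ci_low)) cat(sprintf(" [%.3g, %.3g]", x$ci_low, x$ci_high))
  }
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# validate a 2x2 (or r x c) count matrix
check_counts <- function(counts, square2 = TRUE) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (square2 && !all(dim(counts) == c(2L, 2L)))
    stop("a 2x2 table is required")
  if (!square2 && any(dim(counts) < 2L))
    stop("table must be at least 2x2")
  storage.mode(counts) <- "double"
  counts
}

# median convention used throughout: even-length input -> mean of middle two
# (stats::median already does this; kept as a named wrapper so the convention
# is greppable and NA handling is uniform)
score_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
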
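# Interval helpers. All internal coordinates are 0-based half-open [start, end);
# GFF/GTF 1-based inclusive coordinates are converted at the parsing boundary.

#' Construct an interval matrix
#'
#' Builds the package's internal representation of a set of genomic intervals
#' on one chromosome: an integer matrix with columns `start` and `end`,
#' 0-based half-open.
#'
#' @param start,end Integer vectors of equal length; `start < end`, `start >= 0`.
#' @return An integer matrix with columns `start`, `end`.
#' @keywords internal
interval_matrix <- function(start = integer(0), end = integer(0)) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  m <- cbind(start = start, end = end)
  m[order(m[, "start"], m[, "end"]), , drop = FALSE]
}

# Convert an interval matrix to an IRanges (closed, 1-based) and back.
.iv_to_iranges <- function(m) {
  IRanges::IRanges(start = m[, "start"] + 1L, end = m[, "end"])
}

.iranges_to_iv <- function(ir) {
  interval_matrix(IRanges::start(ir) - 1L, IRanges::end(ir))
}

#' Merge (union) a set of intervals
#'
#' Overlapping or abutting intervals are collapsed, so the result is a sorted
#' set of disjoint, non-adjacent intervals covering the same bases.
#'
#' @param m Interval matrix (see [interval_matrix()]).
#' @return Interval matrix of the union.
#' @keywords internal
merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  .iranges_to_iv(IRanges::reduce(.iv_to_iranges(m)))
}

# Intersect each interval with a window [start, end); empty pieces dropped.
clip_intervals <- function(m, start, end) {
  if (nrow(m) == 0L) return(m)
  s <- pmax(m[, "start"], start)
  e <- pmin(m[, "end"], end)
  keep <- s < e
  if (!any(keep)) return(interval_matrix())
  interval_matrix(s[keep], e[keep])
}

# Gaps strictly between consecutive intervals of a merged set.
gaps_between <- function(m) {
  if (nrow(m) < 2L) return(interval_matrix())
  s <- m[-nrow(m), "end"]
  e <- m[-1L, "start"]
  keep <- s < e
  interval_matrix(s[keep], e[keep])
}

# Total number of bases covered by a merged interval set.
interval_width <- function(m) {
  if (nrow(m) == 0L) return(0L)
  sum(m[, "end"] - m[, "start"])
}
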
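# Interval data model. Convention throughout the package: 0-based, half-open
# [start, end), BED-native. Conversion to IRanges (1-based closed) happens only
# inside the helpers below.

#' Construct a table of genomic intervals
#'
#' The atom of all interval algebra in this package: a data.frame with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand` using 0-based half-open
#' coordinates (BED convention).
#'
#' @param chrom Chromosome labels (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `start < end`.
#' @param name Optional feature names (default `"."`).
#' @param score Optional numeric scores (default 0).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @return A validated data.frame of intervals.
#' @examples
#' gintervals("chr1", 100, 200, name = "p1", score = 8.2, strand = "+")
#' @export
gintervals <- function(chrom, start, end, name = ".", score = 0, strand = ".") {
  n <- length(chrom)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the invariants `0 <= start < end`, non-empty chromosome labels and a
#' legal strand field. Called by every operation that consumes intervals.
#'
#' @param x Interval data.frame as produced by [gintervals()].
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, ": expected a data.frame of intervals")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$chrom) || any(!nzchar(x$chrom))) {
    stop(what, ": empty or NA chromosome label")
  }
  if (anyNA(x$start) || anyNA(x$end)) stop(what, ": NA coordinates")
  if (any(x$start < 0)) {
    stop(what, ": negative start at row ", which(x$start < 0)[1])
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(what, ": start >= end at row ", bad[1],
         " (", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")")
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop(what, ": strand must be '+', '-' or '.'")
  }
  invisible(x)
}

#' Sort intervals by (chrom, start, end)
#' @param x Interval data.frame.
#' @return The sorted data.frame, row names dropped.
#' @export
sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# Internal: split an interval table into IRanges per chromosome.
.ranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
}

#' Which intervals of `a` overlap any interval of `b`?
#'
#' Overlap means at least one shared base; strand is ignored.
#'
#' @param a,b Interval data.frames.
#' @return Logical vector along the rows of `a`.
#' @export
overlaps_any <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  hit <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(hit)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- b$chrom == ch
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    hit[ia] <- IRanges::countOverlaps(ra, rb) > 0L
  }
  hit
}

#' Count query intervals hit by a subject set
#'
#' Each interval of `a` is counted once if it shares at least one base with any
#' interval of `b` (strand-blind). The fraction is relative to `|a|`.
#'
#' @param a Query intervals (non-empty).
#' @param b Subject intervals.
#' @return List with `n_a_hit` (count) and `fraction` (`n_a_hit / nrow(a)`).
#' @examples
#' a <- gintervals("chr1", c(0, 200, 400), c(100, 300, 500))
#' b <- gintervals("chr1", c(250, 450, 600), c(260, 455, 700))
#' overlap_count(a, b) # 2 of 3
#' @export
overlap_count <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0) {
    stop("overlap_count: empty query set; the overlap fraction is undefined")
  }
  hit <- overlaps_any(a, b)
  list(n_a_hit = sum(hit), fraction = sum(hit) / nrow(a))
}
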
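# TSS-anchored coverage matrices, average profile curves, heatmap export.

# Counts of a coverage vector over output bins of a window, fraction-weighted
# for grids that do not align. Bins beyond the chromosome are zero.
window_counts <- function(v, cov_bw, w0, n_bins, bin_width) {
  out <- numeric(n_bins)
  vlen <- length(v) * cov_bw
  for (j in seq_len(n_bins)) {
    a <- w0 + (j - 1) * bin_width
    b <- a + bin_width
    if (b <= 0 || a >= vlen) next
    i0 <- floor(max(a, 0) / cov_bw)
    i1 <- min(ceiling(min(b, vlen) / cov_bw) - 1, length(v) - 1)
    if (i0 > i1) next
    ii <- i0:i1
    ov <- pmin(b, (ii + 1) * cov_bw) - pmax(a, ii * cov_bw)
    out[j] <- sum(v[ii + 1] * ov / cov_bw)
  }
  out
}

#' Build a TSS-anchored, RPM-normalized coverage matrix
#'
#' One row per anchor; `window / bin_width` columns of
#' `raw count x 1e6 / total_mapped_reads`. The window is centered on the
#' anchor (`[pos - window/2, pos + window/2)`). Minus-strand rows are reversed
#' so that column 1 is always the 5'-most bin. Anchors whose window leaves the
#' chromosome are zero-padded and flagged, not dropped, so the row set stays
#' identical across samples.
#'
#' @param cov A [coverage_track()]; its bin grid is re-binned (by fractional
#'   overlap) onto the requested profile bins.
#' @param anchors Data.frame with `chrom`, `pos`, `strand` and optionally
#'   `name` (used as row names).
#' @param window Total window width in bp (default 3000, i.e. TSS +/- 1.5 kb);
#'   must be divisible by `bin_width`.
#' @param bin_width Profile bin width in bp (default 50).
#' @param sample_label Metadata label.
#' @return Object of class `tss_matrix`: list with `values` (matrix),
#'   `offsets` (bp of each column's left edge relative to the anchor, in 5'->3'
#'   orientation), `edge_flag` (logical per row), and metadata.
#' @export
build_tss_matrix <- function(cov, anchors, window = 3000, bin_width = 50,
                             sample_label = "sample") {
  stopifnot(inherits(cov, "coverage_track"))
  if (window %% bin_width != 0) {
    stop("build_tss_matrix: window must be divisible by bin_width")
  }
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(anchors))) {
    stop("build_tss_matrix: anchors need columns chrom, pos, strand")
  }
  n_bins <- window / bin_width
  half <- window / 2
  n <- nrow(anchors)
  vals <- matrix(0, n, n_bins)
  edge <- logical(n)
  for (i in seq_len(n)) {
    v <- cov$counts[[anchors$chrom[i]]]
    if (is.null(v)) stop("build_tss_matrix: anchor on unknown chromosome: ",
                         anchors$chrom[i])
    w0 <- anchors$pos[i] - half
    edge[i] <- w0 < 0 || (w0 + window) > length(v) * cov$bin_width
    row <- window_counts(v, cov$bin_width, w0, n_bins, bin_width)
    if (identical(anchors$strand[i], "-")) row <- rev(row)
    vals[i, ] <- row
  }
  vals <- vals * 1e6 / cov$total_mapped_reads
  rn <- if ("name" %in% names(anchors)) anchors$name else
    sprintf("anchor_%d", seq_len(n))
  rownames(vals) <- rn
  structure(list(values = vals,
                 offsets = seq(-half, half - bin_width, by = bin_width),
                 edge_flag = stats::setNames(edge, rn),
                 window = window, bin_width = bin_width,
                 sample_label = sample_label),
            class = "tss_matrix")
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat("tss_matrix [", x$sample_label, "]: ", nrow(x$values), " anchors x ",
      ncol(x$values), " bins of ", x$bin_width, " bp (window ", x$window,
      " bp); ", sum(x$edge_flag), " edge-padded row(s)\n", sep = "")
  invisible(x)
}

#' Average profile curve of a TSS matrix
#'
#' @param m A [build_tss_matrix()] result with at least one row.
#' @return Data.frame with `offset_bp` (left edge of each bin, 5'->3') and
#'   `mean_rpm` (column means).
#' @export
profile_curve <- function(m) {
  stopifnot(inherits(m, "tss_matrix"))
  if (nrow(m$values) == 0) stop("profile_curve: empty matrix")
  data.frame(offset_bp = m$offsets, mean_rpm = colMeans(m$values),
             row.names = NULL)
}

#' Order a TSS matrix for heatmap export
#'
#' @param m A [build_tss_matrix()] result.
#' @param row_order `"mean_desc"` (by decreasing row mean, ties broken by row
#'   name) or `"given"`.
#' @param given Row names in the desired order when `row_order = "given"`.
#' @return The reordered value matrix.
#' @export
export_heatmap_matrix <- function(m, row_order = c("mean_desc", "given"),
                                  given = NULL) {
  stopifnot(inherits(m, "tss_matrix"))
  row_order <- match.arg(row_order)
  v <- m$values
  if (row_order == "mean_desc") {
    mu <- rowMeans(v)
    v <- v[order(-mu, rownames(v)), , drop = FALSE]
  } else {
    if (is.null(given) || !setequal(given, rownames(v))) {
      stop("export_heatmap_matrix: 'given' must list exactly the row names")
    }
    v <- v[given, , drop = FALSE]
  }
  v
}

#' Write a TSS matrix (or heatmap-ordered matrix) as TSV
#' @param values Matrix with row names; columns are bins.
#' @param offsets Bin left-edge offsets for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(values, offsets, path) {
  header <- paste(c("name", offsets), collapse = "\t")
  lines <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], format_num(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
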
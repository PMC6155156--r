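# Simple per-bin enrichment screen. This is a documented stand-in for a full
# peak caller: fold change on RPM-scaled bins, upper-tail Poisson p-value
# against the depth-scaled input, Benjamini-Hochberg across bins, threshold,
# merge adjacent surviving bins. It makes no attempt at fragment-model or
# local-background refinements.

#' Screen binned ChIP coverage against input for enriched regions
#'
#' Per bin: `FC = chip RPM / max(input RPM, pseudocount RPM)`; the p-value is
#' the upper tail `P(X >= chip)` of a Poisson with mean equal to the input
#' count rescaled to the ChIP depth (floored at the pseudocount). P-values are
#' Benjamini-Hochberg adjusted across all bins; bins with `FDR < fdr_max` and
#' `FC > fc_min` are retained and adjacent retained bins are merged into peaks.
#'
#' @param chip,input [coverage_track()]s on the same bin grid.
#' @param fdr_max FDR threshold, in (0, 1] (default 0.01).
#' @param fc_min Fold-change threshold (default 5).
#' @param pseudocount Reads added as a floor on the input (default 1); avoids
#'   infinite fold change on zero-input bins.
#' @param sample_label Label attached to the result.
#' @return Interval data.frame of peaks with `fold_change` (mean FC of merged
#'   bins) and `fdr` (minimum adjusted p of merged bins) columns; `score` is
#'   the mean fold change.
#' @export
enrichment_screen <- function(chip, input, fdr_max = 0.01, fc_min = 5,
                              pseudocount = 1, sample_label = "chip") {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_width != input$bin_width ||
      !identical(sort(names(chip$counts)), sort(names(input$counts))) ||
      !all(lengths(chip$counts)[names(input$counts)] == lengths(input$counts))) {
    stop("enrichment_screen: chip and input tracks are not on the same bin grid")
  }
  if (length(fdr_max) != 1 || fdr_max <= 0 || fdr_max > 1) {
    stop("enrichment_screen: fdr_max must lie in (0, 1]")
  }
  if (sum(lengths(chip$counts)) == 0) {
    stop("enrichment_screen: zero-length tracks")
  }
  chroms <- names(chip$counts)
  cvec <- unlist(chip$counts[chroms], use.names = FALSE)
  ivec <- unlist(input$counts[chroms], use.names = FALSE)

  depth_scale <- chip$total_mapped_reads / input$total_mapped_reads
  lambda <- pmax(ivec, pseudocount) * depth_scale
  fc <- (cvec / chip$total_mapped_reads) /
    (pmax(ivec, pseudocount) / input$total_mapped_reads)
  pval <- stats::ppois(cvec - 1, lambda, lower.tail = FALSE)
  fdr <- stats::p.adjust(pval, method = "BH")
  keep <- fdr < fdr_max & fc > fc_min

  bw <- chip$bin_width
  out <- list()
  off <- 0L
  for (ch in chroms) {
    n <- length(chip$counts[[ch]])
    idx <- which(keep[seq_len(n) + off])
    if (length(idx)) {
      runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
      for (r in runs) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = (r[1] - 1) * bw,
          end = r[length(r)] * bw,
          fold_change = mean(fc[r + off]),
          fdr = min(fdr[r + off]),
          stringsAsFactors = FALSE
        )
      }
    }
    off <- off + n
  }
  if (!length(out)) {
    peaks <- gintervals(character(), numeric(), numeric())
    peaks$fold_change <- numeric(0)
    peaks$fdr <- numeric(0)
  } else {
    d <- do.call(rbind, out)
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    peaks <- gintervals(d$chrom, d$start, d$end,
                        name = sprintf("%s_peak_%d", sample_label,
                                       seq_len(nrow(d))),
                        score = d$fold_change)
    peaks$fold_change <- d$fold_change
    peaks$fdr <- d$fdr
  }
  attr(peaks, "sample_label") <- sample_label
  attr(peaks, "fdr_max") <- fdr_max
  attr(peaks, "fc_min") <- fc_min
  peaks
}
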
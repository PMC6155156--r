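# CpG-island observed/expected ratio analysis.

#' CpG observed/expected ratio of a sequence
#'
#' Gardiner-Garden & Frommer convention: `oe = N_CpG * L / (N_C * N_G)`,
#' where `N_CpG` counts CG dinucleotides, `N_C`/`N_G` count C and G bases and
#' `L` is the sequence length. `N` bases are excluded from all counts and from
#' `L` so masked sequence does not deflate the ratio.
#'
#' @param sequence A single character string over A/C/G/T/N (case-insensitive).
#' @return The o/e ratio (non-negative number).
#' @examples
#' compute_oe("CGCG")   # 2.0
#' compute_oe("AACGAA") # 6.0
#' @export
compute_oe <- function(sequence) {
  if (length(sequence) != 1 || !is.character(sequence)) {
    stop("compute_oe: expected a single character string")
  }
  s <- toupper(sequence)
  if (nchar(s) < 2) stop("compute_oe: sequence shorter than 2 bases")
  if (grepl("[^ACGTN]", s)) stop("compute_oe: alphabet must be A/C/G/T/N")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  len <- sum(chars != "N")
  n_cpg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
  if (!grepl("CG", s, fixed = TRUE)) n_cpg <- 0L
  if (n_c * n_g == 0) {
    stop("compute_oe: o/e undefined (no C or no G in sequence)")
  }
  n_cpg * len / (n_c * n_g)
}

#' Annotate CpG islands with composition and o/e from genome sequence
#'
#' @param genome Named character vector of chromosome sequences.
#' @param cgis Interval data.frame of island coordinates.
#' @return `cgis` with `n_cpg`, `n_c`, `n_g`, `length` and `oe` columns added;
#'   islands whose o/e is undefined get `NA` and a warning.
#' @export
annotate_cgis <- function(genome, cgis) {
  validate_intervals(cgis, "cgis")
  unk <- setdiff(unique(cgis$chrom), names(genome))
  if (length(unk)) {
    stop("annotate_cgis: islands on chromosome(s) absent from the genome: ",
         paste(unk, collapse = ", "))
  }
  n <- nrow(cgis)
  out <- cgis
  out$n_cpg <- out$n_c <- out$n_g <- out$length <- out$oe <- NA_real_
  for (i in seq_len(n)) {
    s <- substr(genome[[cgis$chrom[i]]], cgis$start[i] + 1, cgis$end[i])
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    out$n_c[i] <- sum(chars == "C")
    out$n_g[i] <- sum(chars == "G")
    out$length[i] <- sum(chars != "N")
    out$n_cpg[i] <- if (grepl("CG", toupper(s), fixed = TRUE)) {
      length(gregexpr("CG", toupper(s), fixed = TRUE)[[1]])
    } else 0L
    if (out$n_c[i] * out$n_g[i] > 0) {
      out$oe[i] <- out$n_cpg[i] * out$length[i] / (out$n_c[i] * out$n_g[i])
    }
  }
  if (anyNA(out$oe)) warning("annotate_cgis: undefined o/e for some islands")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for small untied samples, normal approximation with continuity and
#' tie correction otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_p <- function(x, y) {
  if (!length(x) || !length(y)) stop("wilcoxon_p: empty sample")
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}

box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = if (length(inside)) min(inside) else NA_real_,
       whisker_high = if (length(inside)) max(inside) else NA_real_,
       outliers = sort(v[v < lo | v > hi]), n = length(v))
}

#' Compare CGI o/e distributions between peak classes
#'
#' Builds three o/e samples — all islands, islands overlapping total-sperm
#' peaks, islands overlapping HRCS peaks — and reports box-plot statistics
#' (median, quartiles, 1.5 x IQR whiskers, outliers) plus pairwise two-sided
#' Wilcoxon rank-sum p-values.
#'
#' @param cgis Annotated island table (see [annotate_cgis()]; must carry `oe`).
#' @param peaks_total,peaks_hrcs Peak interval data.frames.
#' @return List with `samples` (named list of o/e vectors), `box` (per-sample
#'   box statistics), `pvalues` (named pairwise p-values) and `n_overlap`
#'   counts.
#' @export
cgi_peak_oe_comparison <- function(cgis, peaks_total, peaks_hrcs) {
  if (!"oe" %in% names(cgis)) stop("cgi_peak_oe_comparison: cgis lack an oe column")
  oe_all <- cgis$oe[!is.na(cgis$oe)]
  iv <- gintervals(cgis$chrom, cgis$start, cgis$end)
  in_total <- overlaps_any(iv, peaks_total) & !is.na(cgis$oe)
  in_hrcs <- overlaps_any(iv, peaks_hrcs) & !is.na(cgis$oe)
  samples <- list(all = oe_all,
                  total = cgis$oe[in_total],
                  hrcs = cgis$oe[in_hrcs])
  empty <- names(samples)[vapply(samples, length, integer(1)) == 0]
  if (length(empty)) {
    stop("cgi_peak_oe_comparison: empty o/e sample(s): ",
         paste(empty, collapse = ", "))
  }
  pv <- c(all_vs_total = wilcoxon_p(samples$all, samples$total),
          all_vs_hrcs = wilcoxon_p(samples$all, samples$hrcs),
          total_vs_hrcs = wilcoxon_p(samples$total, samples$hrcs))
  list(samples = samples,
       box = lapply(samples, box_stats),
       pvalues = pv,
       n_overlap = c(total = sum(in_total), hrcs = sum(in_hrcs)))
}

#' Per-chromosome densities of peaks and high-o/e CpG islands
#'
#' @param peaks Peak interval data.frame.
#' @param cgis Annotated island table with `oe`.
#' @param chrom_sizes Named vector of chromosome lengths (bp); must cover all
#'   peak chromosomes.
#' @param oe_min Islands with `oe > oe_min` count as high-o/e (default 1.0).
#' @return Data.frame: chrom, length_mb, n_peaks, peaks_per_mb, n_cgi_high,
#'   cgi_high_per_mb.
#' @export
chromosome_density <- function(peaks, cgis, chrom_sizes, oe_min = 1.0) {
  validate_intervals(peaks, "peaks")
  bad <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(bad)) {
    stop("chromosome_density: chrom_sizes does not cover: ",
         paste(bad, collapse = ", "))
  }
  chroms <- names(chrom_sizes)
  mb <- as.numeric(chrom_sizes) / 1e6
  n_pk <- vapply(chroms, function(ch) sum(peaks$chrom == ch), numeric(1))
  hi <- !is.na(cgis$oe) & cgis$oe > oe_min
  n_cg <- vapply(chroms, function(ch) sum(cgis$chrom == ch & hi), numeric(1))
  data.frame(chrom = chroms, length_mb = mb,
             n_peaks = n_pk, peaks_per_mb = n_pk / mb,
             n_cgi_high = n_cg, cgi_high_per_mb = n_cg / mb,
             row.names = NULL, stringsAsFactors = FALSE)
}
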
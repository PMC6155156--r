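# Target-gene mapping, sample overlap summaries, and the three-way
# category_H / category_PH / category_TS classification.

#' Map peaks to target genes
#'
#' A gene is a target iff at least one peak overlaps its promoter window
#' (TSS +/- `flank`). Linkage is promoter-only; gene-body peaks do not make a
#' gene a target.
#'
#' @param peaks Peak interval data.frame.
#' @param genes Gene model data.frame.
#' @param flank Promoter half-width in bp (default 1000).
#' @return Sorted character vector of unique target gene ids.
#' @export
peaks_to_genes <- function(peaks, genes, flank = 1000) {
  validate_intervals(peaks, "peaks")
  if (nrow(peaks) == 0) return(character(0))
  prom <- promoter_windows(genes, flank)
  hit <- overlaps_any(prom, peaks)
  sort(unique(prom$name[hit]))
}

#' Integer-rounded overlap percentage
#'
#' The reporting rule used for all overlap summaries: `round(100 * n_hit / n)`
#' to the nearest integer (so 966/1320 prints as 73).
#'
#' @param n_hit Number of overlapping items.
#' @param n Total number of items (> 0).
#' @return Integer percentage.
#' @export
overlap_percent <- function(n_hit, n) {
  if (any(n <= 0)) stop("overlap_percent: total must be positive")
  as.integer(round(100 * n_hit / n))
}

#' Pairwise peak- and gene-level overlap summary across samples
#'
#' For every ordered sample pair reports, at the peak level, how many of A's
#' peaks overlap a peak of B, and at the gene level how many of A's target
#' genes are also targets of B. Percentages are integer-rounded
#' ([overlap_percent()]); the raw fractions are kept alongside.
#'
#' @param peaks_by_sample Named list (>= 2 entries) of peak interval
#'   data.frames.
#' @param genes Gene model data.frame for target-gene linkage.
#' @param flank Promoter half-width (default 1000).
#' @return Data.frame: sample_a, sample_b, level ("peak"/"gene"), n, n_hit,
#'   fraction, percent.
#' @export
overlap_summary <- function(peaks_by_sample, genes, flank = 1000) {
  if (!is.list(peaks_by_sample) || length(peaks_by_sample) < 2 ||
      is.null(names(peaks_by_sample))) {
    stop("overlap_summary: need a named list of >= 2 peak sets")
  }
  empty <- names(peaks_by_sample)[vapply(peaks_by_sample, nrow, integer(1)) == 0]
  if (length(empty)) {
    stop("overlap_summary: empty peak set(s): ", paste(empty, collapse = ", "))
  }
  targets <- lapply(peaks_by_sample, peaks_to_genes, genes = genes,
                    flank = flank)
  out <- list()
  labs <- names(peaks_by_sample)
  for (a in labs) for (b in labs) {
    if (a == b) next
    oc <- overlap_count(peaks_by_sample[[a]], peaks_by_sample[[b]])
    ta <- targets[[a]]; shared <- length(intersect(ta, targets[[b]]))
    out[[length(out) + 1L]] <- data.frame(
      sample_a = a, sample_b = b, level = c("peak", "gene"),
      n = c(nrow(peaks_by_sample[[a]]), length(ta)),
      n_hit = c(oc$n_a_hit, shared),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  d <- d[d$n > 0 | d$level == "peak", , drop = FALSE]
  if (any(d$n == 0)) {
    d <- d[d$n > 0, , drop = FALSE]
  }
  d$fraction <- d$n_hit / d$n
  d$percent <- overlap_percent(d$n_hit, d$n)
  rownames(d) <- NULL
  d
}

# Mean RPM of a coverage track over a set of intervals (bp-weighted).
region_mean_rpm <- function(cov, regions) {
  stopifnot(inherits(cov, "coverage_track"))
  validate_intervals(regions, "regions")
  if (nrow(regions) == 0) return(NA_real_)
  bw <- cov$bin_width
  tot <- 0; bp <- 0
  for (i in seq_len(nrow(regions))) {
    v <- cov$counts[[regions$chrom[i]]]
    if (is.null(v)) next
    a <- regions$start[i]; b <- min(regions$end[i], length(v) * bw)
    if (a >= b) next
    i0 <- floor(a / bw); i1 <- ceiling(b / bw) - 1
    idx <- (i0:i1) + 1
    ov <- pmin(b, (i0:i1 + 1) * bw) - pmax(a, (i0:i1) * bw)
    tot <- tot + sum(v[idx] * ov / bw)
    bp <- bp + sum(ov)
  }
  if (bp == 0) return(NA_real_)
  (tot / (bp / bw)) * 1e6 / cov$total_mapped_reads
}

# Genome-wide mean RPM per bin.
genome_mean_rpm <- function(cov) {
  stopifnot(inherits(cov, "coverage_track"))
  n <- sum(lengths(cov$counts))
  (sum(vapply(cov$counts, sum, numeric(1))) / n) * 1e6 / cov$total_mapped_reads
}

#' Classify target genes into category_H / category_PH / category_TS
#'
#' category_H: genes with an HRCS peak at their promoter. Remaining total-sperm
#' targets are split by HRCS signal over their total-sperm promoter peak(s):
#' category_PH ("potential HRCS targets") if the mean HRCS RPM `S` is at least
#' `k_background` times a reference level `B`, category_TS otherwise. With
#' `method = "background"` (default), `B` is the genome-wide mean HRCS RPM;
#' with `method = "quantile"`, `B` is the `q`-th quantile of mean HRCS RPM over
#' all gene promoters and `k_background` is ignored.
#'
#' @param genes_total,genes_hrcs Character vectors of target gene ids.
#' @param hrcs_cov HRCS [coverage_track()].
#' @param peaks_total Total-sperm peak interval data.frame.
#' @param genes Gene model data.frame.
#' @param k_background Background multiple for the PH rule (default 2; > 0).
#' @param method `"background"` or `"quantile"`.
#' @param q Quantile for `method = "quantile"` (default 0.75).
#' @param flank Promoter half-width (default 1000).
#' @return Data.frame: gene_id, in_total, in_hrcs, mean_hrcs_rpm,
#'   background_rpm, category (`H`, `PH`, `TS`; genes hit by neither sample are
#'   not listed).
#' @export
categorize_targets <- function(genes_total, genes_hrcs, hrcs_cov, peaks_total,
                               genes, k_background = 2,
                               method = c("background", "quantile"), q = 0.75,
                               flank = 1000) {
  method <- match.arg(method)
  if (method == "background" && (length(k_background) != 1 || k_background <= 0)) {
    stop("categorize_targets: k_background must be a single positive number")
  }
  all_ids <- sort(unique(c(genes_total, genes_hrcs)))
  prom <- promoter_windows(genes, flank)
  prom <- prom[prom$name %in% all_ids, , drop = FALSE]

  mean_rpm <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  for (id in all_ids) {
    pw <- prom[prom$name == id, , drop = FALSE]
    if (!nrow(pw)) next
    hit <- overlaps_any(peaks_total, pw)
    if (any(hit)) {
      mean_rpm[id] <- region_mean_rpm(hrcs_cov, peaks_total[hit, , drop = FALSE])
    }
  }
  if (method == "background") {
    b <- genome_mean_rpm(hrcs_cov)
    thr <- k_background * b
  } else {
    pall <- promoter_windows(genes, flank)
    ref <- vapply(seq_len(nrow(pall)), function(i) {
      region_mean_rpm(hrcs_cov, pall[i, , drop = FALSE])
    }, numeric(1))
    b <- stats::quantile(ref, q, names = FALSE, na.rm = TRUE)
    thr <- b
  }
  category <- ifelse(all_ids %in% genes_hrcs, "H",
              ifelse(all_ids %in% genes_total &
                     !is.na(mean_rpm) & mean_rpm >= thr, "PH", "TS"))
  data.frame(gene_id = all_ids,
             in_total = all_ids %in% genes_total,
             in_hrcs = all_ids %in% genes_hrcs,
             mean_hrcs_rpm = as.numeric(mean_rpm),
             background_rpm = b,
             category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}
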
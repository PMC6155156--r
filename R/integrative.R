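# Region-level DNA methylation summaries, cross-sample correlation, and
# per-category embryonic expression dynamics.

#' Average CG methylation per region
#'
#' For every region, the unweighted mean of per-site methylation levels
#' (`methylated / total`) of CG sites inside `[start, end)` with
#' `total >= min_coverage`. Regions with no qualifying site get `NA`; the
#' count of such regions is attached as attribute `n_missing`.
#'
#' @param records Methylation data.frame (`chrom`, `pos0`, `methylated`,
#'   `total`; see [read_methylation()]).
#' @param regions Interval data.frame.
#' @param min_coverage Minimum per-site read total (default 1; must be >= 1).
#' @param weighted If `TRUE`, weight site levels by read totals instead of the
#'   default unweighted site mean.
#' @return Numeric vector of per-region levels in `[0, 1]` (or `NA`), aligned
#'   with `regions` rows.
#' @export
region_methylation <- function(records, regions, min_coverage = 1,
                               weighted = FALSE) {
  if (min_coverage < 1) stop("region_methylation: min_coverage must be >= 1")
  validate_intervals(regions, "regions")
  need <- c("chrom", "pos0", "methylated", "total")
  if (!all(need %in% names(records))) {
    stop("region_methylation: records need columns ",
         paste(need, collapse = ", "))
  }
  rec <- records[records$total >= min_coverage, , drop = FALSE]
  lev <- rec$methylated / rec$total
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    si <- which(rec$chrom == ch)
    if (!length(si)) next
    rr <- IRanges::IRanges(regions$start[ri] + 1, regions$end[ri])
    rs <- IRanges::IRanges(rec$pos0[si] + 1, rec$pos0[si] + 1)
    hits <- IRanges::findOverlaps(rr, rs)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (weighted) {
      wsum <- tapply(lev[si][sh] * rec$total[si][sh], qh, sum)
      wtot <- tapply(rec$total[si][sh], qh, sum)
      out[ri[as.integer(names(wsum))]] <- as.numeric(wsum / wtot)
    } else {
      mu <- tapply(lev[si][sh], qh, mean)
      out[ri[as.integer(names(mu))]] <- as.numeric(mu)
    }
  }
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Pearson correlation of paired region methylation levels
#'
#' @param x,y Equal-length numeric vectors; pairs with any `NA` are dropped.
#' @return List with `r` (Pearson correlation) and `n` (complete pairs used).
#' @export
methylation_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("methylation_correlation: x and y must be paired (equal length)")
  }
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) {
    stop("methylation_correlation: fewer than 3 complete pairs")
  }
  list(r = stats::cor(x[ok], y[ok], method = "pearson"), n = sum(ok))
}

#' Stage-wise fraction of highly expressed genes per target category
#'
#' The gene universe is first restricted to genes with
#' `FPKM > threshold` at `condition_stage` (strict inequality). For each
#' category (including `"all"`) and stage, the fraction of that conditioned
#' universe exceeding the threshold is reported. Categories with no
#' conditioned gene get `NA`.
#'
#' @param expr Expression data.frame (`gene_id` plus one numeric column per
#'   stage, in stage order).
#' @param categories Named character vector `gene_id -> category` (e.g. from
#'   [categorize_targets()]; genes absent from it contribute only to `"all"`).
#' @param threshold FPKM cutoff (default 10, strict `>`).
#' @param condition_stage Stage used for conditioning (default first stage).
#' @param condition_universe If `FALSE`, skip the conditioning and use all
#'   genes of each category.
#' @return Data.frame: category, stage, n (conditioned universe size),
#'   fraction.
#' @export
expression_dynamics <- function(expr, categories, threshold = 10,
                                condition_stage = NULL,
                                condition_universe = TRUE) {
  stages <- setdiff(names(expr), "gene_id")
  if (!length(stages)) stop("expression_dynamics: no stage columns")
  if (is.null(condition_stage)) condition_stage <- stages[1]
  if (!condition_stage %in% stages) {
    stop("expression_dynamics: condition stage '", condition_stage,
         "' not in table")
  }
  cat_of <- rep("none", nrow(expr))
  idx <- match(expr$gene_id, names(categories))
  cat_of[!is.na(idx)] <- unname(categories[idx[!is.na(idx)]])
  groups <- c(list(all = rep(TRUE, nrow(expr))),
              lapply(stats::setNames(nm = sort(unique(cat_of[cat_of != "none"]))),
                     function(cl) cat_of == cl))
  out <- list()
  for (g in names(groups)) {
    in_g <- groups[[g]]
    uni <- if (condition_universe) {
      in_g & expr[[condition_stage]] > threshold
    } else in_g
    n <- sum(uni)
    for (st in stages) {
      frac <- if (n == 0) NA_real_ else sum(expr[[st]][uni] > threshold) / n
      out[[length(out) + 1L]] <- data.frame(category = g, stage = st, n = n,
                                            fraction = frac,
                                            stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  d$stage <- factor(d$stage, levels = stages)
  rownames(d) <- NULL
  d
}
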
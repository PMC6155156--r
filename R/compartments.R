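# Genomic-compartment annotation. Classes, in precedence order:
# promoter > exon > intron > upstream > downstream > intergenic (repeat/unique).
# After precedence resolution the classes partition each chromosome exactly.

COMPARTMENT_CLASSES <- c("promoter", "exon", "intron", "upstream", "downstream",
                         "intergenic_repeat", "intergenic_unique")

#' Promoter windows of a gene set
#'
#' The promoter is read as TSS +/- `flank` (default 1 kb each side, i.e. a
#' 2 kb window); symmetric, so identical for both strands. Windows are clipped
#' at position 0 (and at the chromosome end by callers holding sizes).
#'
#' @param genes Gene model data.frame.
#' @param flank Half-width in bp (default 1000).
#' @return Interval data.frame, one window per gene, named by `gene_id`.
#' @export
promoter_windows <- function(genes, flank = 1000) {
  validate_genes(genes)
  gintervals(genes$chrom,
             pmax(0, genes$tss - flank),
             genes$tss + flank,
             name = genes$gene_id,
             strand = genes$strand)
}

#' Build a compartment annotation from gene models and repeats
#'
#' Windows: promoter = TSS +/- `promoter_flank`; upstream = the strand-aware
#' `[TSS - upstream_dist, TSS - promoter_flank)`; downstream = strand-aware
#' `[TES, TES + downstream_dist)`; exons and introns from gene bodies. Higher
#' precedence classes subtract from lower ones; the remainder is intergenic,
#' split into repeat/unique by overlap with `repeats`. All windows are clipped
#' to chromosome bounds.
#'
#' @param genes Gene model data.frame.
#' @param repeats Interval data.frame of repeat elements.
#' @param chrom_sizes Named numeric vector of chromosome lengths; must cover
#'   every gene chromosome.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @param upstream_dist,downstream_dist Window extents in bp (default 5000).
#' @return Object of class `compartment_annotation`: per-class interval sets
#'   plus the chromosome sizes and parameters.
#' @export
build_annotation <- function(genes, repeats, chrom_sizes,
                             promoter_flank = 1000,
                             upstream_dist = 5000, downstream_dist = 5000) {
  validate_genes(genes)
  validate_intervals(repeats, "repeats")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("build_annotation: chrom_sizes must be a named vector")
  }
  unk <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unk)) {
    stop("build_annotation: gene(s) on unknown chromosome(s): ",
         paste(unk, collapse = ", "))
  }

  n <- nrow(genes)
  plus <- genes$strand == "+"
  win <- function(start, end) {
    data.frame(chrom = genes$chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  prom <- win(genes$tss - promoter_flank, genes$tss + promoter_flank)
  upst <- win(ifelse(plus, genes$tss - upstream_dist, genes$tss + promoter_flank),
              ifelse(plus, genes$tss - promoter_flank, genes$tss + upstream_dist))
  down <- win(ifelse(plus, genes$tes, genes$tes - downstream_dist),
              ifelse(plus, genes$tes + downstream_dist, genes$tes))
  exn <- do.call(rbind, lapply(seq_len(n), function(i) {
    es <- parse_blocks(genes$exon_starts[i]); ee <- parse_blocks(genes$exon_ends[i])
    if (!length(es)) return(NULL)
    data.frame(chrom = genes$chrom[i], start = es, end = ee,
               stringsAsFactors = FALSE)
  }))
  body <- win(pmin(genes$tss, genes$tes), pmax(genes$tss, genes$tes))

  chroms <- names(chrom_sizes)
  to_rl <- function(d, ch, size) {
    if (is.null(d)) return(IRanges::IRanges())
    di <- d[d$chrom == ch, , drop = FALSE]
    s <- pmax(di$start, 0); e <- pmin(di$end, size)
    ok <- s < e
    IRanges::reduce(IRanges::IRanges(s[ok] + 1, e[ok]))
  }

  classes <- stats::setNames(vector("list", length(COMPARTMENT_CLASSES)),
                             COMPARTMENT_CLASSES)
  for (cl in COMPARTMENT_CLASSES) classes[[cl]] <- list()

  for (ch in chroms) {
    size <- chrom_sizes[[ch]]
    full <- IRanges::IRanges(1, size)
    r_prom <- to_rl(prom, ch, size)
    r_exon <- to_rl(exn, ch, size)
    r_body <- to_rl(body, ch, size)
    r_intr <- IRanges::setdiff(r_body, r_exon)
    r_upst <- to_rl(upst, ch, size)
    r_down <- to_rl(down, ch, size)
    r_rep <- to_rl(repeats, ch, size)

    assigned <- IRanges::IRanges()
    take <- function(r) {
      r <- IRanges::setdiff(r, assigned)
      assigned <<- IRanges::reduce(IRanges::union(assigned, r))
      r
    }
    resolved <- list(promoter = take(r_prom), exon = take(r_exon),
                     intron = take(r_intr), upstream = take(r_upst),
                     downstream = take(r_down))
    inter <- IRanges::setdiff(full, assigned)
    resolved$intergenic_repeat <- IRanges::intersect(inter, r_rep)
    resolved$intergenic_unique <- IRanges::setdiff(inter, r_rep)

    for (cl in COMPARTMENT_CLASSES) {
      r <- resolved[[cl]]
      if (length(r)) {
        classes[[cl]][[ch]] <- data.frame(
          chrom = ch, start = IRanges::start(r) - 1, end = IRanges::end(r),
          stringsAsFactors = FALSE)
      }
    }
  }
  classes <- lapply(classes, function(l) {
    if (!length(l)) {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      d <- do.call(rbind, l); rownames(d) <- NULL; d
    }
  })
  structure(list(classes = classes, chrom_sizes = chrom_sizes,
                 params = list(promoter_flank = promoter_flank,
                               upstream_dist = upstream_dist,
                               downstream_dist = downstream_dist)),
            class = "compartment_annotation")
}

#' @export
print.compartment_annotation <- function(x, ...) {
  len <- vapply(x$classes, function(d) sum(d$end - d$start), numeric(1))
  cat("compartment_annotation over", length(x$chrom_sizes),
      "chromosome(s):\n")
  print(round(len / sum(x$chrom_sizes), 4))
  invisible(x)
}

#' Check that an annotation partitions the genome
#'
#' @param ann A [build_annotation()] result.
#' @return List with `ok` (logical), `total_class_bp`, `total_genome_bp` and
#'   `max_pairwise_overlap_bp`.
#' @export
check_partition <- function(ann) {
  stopifnot(inherits(ann, "compartment_annotation"))
  total_class <- sum(vapply(ann$classes, function(d) sum(d$end - d$start),
                            numeric(1)))
  total_genome <- sum(ann$chrom_sizes)
  max_ov <- 0
  cls <- names(ann$classes)
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (j <= i) next
      a <- ann$classes[[i]]; b <- ann$classes[[j]]
      if (!nrow(a) || !nrow(b)) next
      for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
        ra <- IRanges::IRanges(a$start[a$chrom == ch] + 1, a$end[a$chrom == ch])
        rb <- IRanges::IRanges(b$start[b$chrom == ch] + 1, b$end[b$chrom == ch])
        ov <- IRanges::intersect(ra, rb)
        max_ov <- max(max_ov, sum(IRanges::width(ov)))
      }
    }
  }
  list(ok = (total_class == total_genome) && max_ov == 0,
       total_class_bp = total_class, total_genome_bp = total_genome,
       max_pairwise_overlap_bp = max_ov)
}

#' Export a compartment annotation as one BED table
#' @param ann Annotation object.
#' @return Interval data.frame with the class in the `name` column.
#' @export
annotation_to_bed <- function(ann) {
  stopifnot(inherits(ann, "compartment_annotation"))
  d <- do.call(rbind, lapply(names(ann$classes), function(cl) {
    x <- ann$classes[[cl]]
    if (!nrow(x)) return(NULL)
    gintervals(x$chrom, x$start, x$end, name = cl)
  }))
  sort_intervals(d)
}

#' Tabulate peaks across compartments
#'
#' Each peak is assigned to a single class: by default the class of the base
#' under its midpoint (deterministic, order-independent); alternatively by
#' maximal overlap.
#'
#' @param peaks Interval data.frame of peaks.
#' @param ann A [build_annotation()] result.
#' @param assign `"midpoint"` (default) or `"max_overlap"`.
#' @return Data.frame with `class`, `count`, `fraction`, `genome_fraction` and
#'   `enrichment` (= fraction / genome_fraction); fractions sum to 1.
#' @export
peak_compartment_table <- function(peaks, ann,
                                   assign = c("midpoint", "max_overlap")) {
  assign <- match.arg(assign)
  validate_intervals(peaks, "peaks")
  stopifnot(inherits(ann, "compartment_annotation"))
  bad <- setdiff(unique(peaks$chrom), names(ann$chrom_sizes))
  if (length(bad)) {
    stop("peak_compartment_table: peaks on chromosome(s) absent from the ",
         "annotation: ", paste(bad, collapse = ", "))
  }
  cls_of <- rep(NA_character_, nrow(peaks))
  if (assign == "midpoint") {
    mid <- floor((peaks$start + peaks$end) / 2)
    pts <- gintervals(peaks$chrom, mid, mid + 1)
    for (cl in names(ann$classes)) {
      d <- ann$classes[[cl]]
      if (!nrow(d)) next
      hit <- overlaps_any(pts, gintervals(d$chrom, d$start, d$end))
      cls_of[is.na(cls_of) & hit] <- cl
    }
  } else {
    ov_bp <- matrix(0, nrow(peaks), length(ann$classes),
                    dimnames = list(NULL, names(ann$classes)))
    for (cl in names(ann$classes)) {
      d <- ann$classes[[cl]]
      if (!nrow(d)) next
      for (ch in intersect(unique(peaks$chrom), unique(d$chrom))) {
        ip <- which(peaks$chrom == ch)
        rp <- IRanges::IRanges(peaks$start[ip] + 1, peaks$end[ip])
        rc <- IRanges::IRanges(d$start[d$chrom == ch] + 1, d$end[d$chrom == ch])
        hits <- IRanges::findOverlaps(rp, rc)
        if (!length(hits)) next
        w <- IRanges::width(IRanges::pintersect(
          rp[S4Vectors::queryHits(hits)], rc[S4Vectors::subjectHits(hits)]))
        agg <- tapply(w, S4Vectors::queryHits(hits), sum)
        ov_bp[ip[as.integer(names(agg))], cl] <- as.numeric(agg)
      }
    }
    # ties broken by class precedence (column order)
    cls_of <- names(ann$classes)[apply(ov_bp, 1, which.max)]
  }
  counts <- table(factor(cls_of, levels = names(ann$classes)))
  glen <- vapply(ann$classes, function(d) sum(d$end - d$start), numeric(1))
  out <- data.frame(class = names(ann$classes),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / max(1, nrow(peaks)),
                    genome_fraction = glen / sum(ann$chrom_sizes),
                    stringsAsFactors = FALSE)
  out$enrichment <- ifelse(out$genome_fraction > 0,
                           out$fraction / out$genome_fraction, NA_real_)
  rownames(out) <- NULL
  out
}
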
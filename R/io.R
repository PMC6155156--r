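# Readers/writers for the plain-text formats the pipeline touches.
# All coordinates on disk and in memory are 0-based half-open, so BED and
# bedGraph round-trip without shifting.

#' Read a BED3/BED6 file
#'
#' @param path Path to a tab-separated BED file (3 to 6 columns; `#` comment,
#'   `track` and `browser` lines are skipped).
#' @return Interval data.frame (see [gintervals()]); absent name/score/strand
#'   columns are filled with `"."`, 0, `"."`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(gintervals(character(), numeric(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("read_bed: line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns")
  }
  get <- function(k, default) {
    vapply(parts, function(p) if (length(p) >= k) p[k] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("read_bed: line ", lineno[bad[1]], ": non-numeric coordinates")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("read_bed: line ", lineno[bad[1]], ": invalid interval [",
         start[bad[1]], ", ", end[bad[1]], ")")
  }
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  gintervals(get(1, "."), start, end,
             name = get(4, "."), score = score, strand = get(6, "."))
}

#' Write intervals as BED6
#' @param x Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                   x$chrom, format_coord(x$start), format_coord(x$end),
                   if (is.null(x$name)) "." else x$name,
                   if (is.null(x$score)) "0" else format_num(x$score),
                   if (is.null(x$strand)) "." else x$strand)
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) {
  out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), character(1))
  out
}

#' Construct a binned coverage track
#'
#' @param counts Named list, one non-negative numeric vector per chromosome;
#'   element `i` covers `[(i-1)*bin_width, i*bin_width)`.
#' @param bin_width Uniform bin width in bp.
#' @param total_mapped_reads Library depth used for RPM normalization; defaults
#'   to the sum of all counts and must be positive.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(counts, bin_width, total_mapped_reads = NULL) {
  if (!is.list(counts) || is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("coverage_track: counts must be a named list of numeric vectors")
  }
  if (any(vapply(counts, function(v) any(v < 0) || anyNA(v), logical(1)))) {
    stop("coverage_track: counts must be non-negative and non-missing")
  }
  if (length(bin_width) != 1 || bin_width <= 0) {
    stop("coverage_track: bin_width must be a single positive number")
  }
  if (is.null(total_mapped_reads)) {
    total_mapped_reads <- sum(vapply(counts, sum, numeric(1)))
  }
  if (total_mapped_reads <= 0) {
    stop("coverage_track: total_mapped_reads must be > 0")
  }
  structure(list(counts = counts, bin_width = bin_width,
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$counts), "chromosome(s), bin width",
      x$bin_width, "bp, total mapped reads",
      format(x$total_mapped_reads, big.mark = ","), "\n")
  invisible(x)
}

#' Write a coverage track as bedGraph plus a depth sidecar
#'
#' The sidecar (`<path>.reads.tsv` by default) holds
#' `sample<TAB>total_mapped_reads` so RPM normalization survives the round trip.
#'
#' @param track A [coverage_track()].
#' @param path Output bedGraph path.
#' @param sample Sample label written to the sidecar.
#' @param sidecar Sidecar path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, sample = "sample",
                           sidecar = paste0(path, ".reads.tsv")) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track$bin_width
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format_coord((nz - 1) * bw),
                       format_coord(nz * bw),
                       format_num(v[nz])), con)
  }
  writeLines(sprintf("%s\t%s", sample, format_num(track$total_mapped_reads)),
             sidecar)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()]
#'
#' @param path bedGraph path; every record must sit on one uniform bin grid.
#' @param sidecar Sidecar path with the mapped-read total.
#' @param chrom_sizes Optional named vector of chromosome lengths; defaults to
#'   the largest end seen per chromosome.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sidecar = paste0(path, ".reads.tsv"),
                          chrom_sizes = NULL) {
  if (!file.exists(path)) stop("read_bedgraph: no such file: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (nrow(d) == 0) stop("read_bedgraph: empty track: ", path)
  w <- unique(d$end - d$start)
  if (length(w) != 1) stop("read_bedgraph: non-uniform bin width in ", path)
  if (any(d$start %% w != 0)) stop("read_bedgraph: bins off the grid in ", path)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(d$end, d$chrom), max, numeric(1))
  }
  counts <- lapply(names(chrom_sizes), function(ch) {
    v <- numeric(ceiling(chrom_sizes[[ch]] / w))
    di <- d[d$chrom == ch, , drop = FALSE]
    v[di$start / w + 1] <- di$value
    v
  })
  names(counts) <- names(chrom_sizes)
  total <- NULL
  if (file.exists(sidecar)) {
    sc <- utils::read.table(sidecar, sep = "\t", header = FALSE)
    total <- as.numeric(sc[1, 2])
  }
  coverage_track(counts, w, total)
}

#' Write a gene model table (refFlat-style, 0-based half-open)
#'
#' Columns: gene_id, chrom, strand, tss, tes, exon_starts, exon_ends (the last
#' two comma-separated). `tss` is the 5' end respecting strand, so `tss > tes`
#' on the minus strand.
#'
#' @param genes Gene model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tes",
                               "exon_starts", "exon_ends")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene model table written by [write_gene_table()]
#' @param path Input path.
#' @return Gene model data.frame; invariants (strand, exon containment) are
#'   checked.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("read_gene_table: no such file: ", path)
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "character",
                                        "character"))
  validate_genes(g)
  g
}

#' Validate a gene model table
#' @param genes Gene model data.frame.
#' @return `genes`, invisibly, or an error.
#' @export
validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene table: strand must be '+' or '-'")
  }
  bad <- which((genes$strand == "+" & genes$tss >= genes$tes) |
               (genes$strand == "-" & genes$tss <= genes$tes))
  if (length(bad)) {
    stop("gene table: tss must be the 5' end respecting strand (row ",
         bad[1], ")")
  }
  if (all(c("exon_starts", "exon_ends") %in% names(genes)) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      es <- parse_blocks(genes$exon_starts[i])
      ee <- parse_blocks(genes$exon_ends[i])
      if (length(es) != length(ee) || any(es >= ee)) {
        stop("gene table: malformed exon blocks for ", genes$gene_id[i])
      }
      lo <- min(genes$tss[i], genes$tes[i]); hi <- max(genes$tss[i], genes$tes[i])
      if (length(es) && (min(es) < lo || max(ee) > hi)) {
        stop("gene table: exons outside gene body for ", genes$gene_id[i])
      }
    }
  }
  invisible(genes)
}

parse_blocks <- function(s) {
  if (is.null(s) || length(s) == 0 || is.na(s) || !nzchar(s)) {
    return(numeric(0))
  }
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Write a per-CG methylation table
#'
#' Columns: chrom, pos0 (0-based position of the C of a CG on the plus strand),
#' methylated, total.
#' @param meth Methylation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(meth, path) {
  utils::write.table(meth[, c("chrom", "pos0", "methylated", "total")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-CG methylation table
#' @param path Input path.
#' @return Data.frame with a derived `level = methylated/total` column.
#' @export
read_methylation <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (any(m$methylated > m$total) || any(m$methylated < 0)) {
    stop("read_methylation: methylated count outside [0, total]")
  }
  m$level <- ifelse(m$total > 0, m$methylated / m$total, NA_real_)
  m
}

#' Write a gene-by-stage FPKM matrix
#' @param expr Expression data.frame: `gene_id` plus one numeric column per
#'   stage, columns in stage order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-stage FPKM matrix
#' @param path Input path.
#' @return Expression data.frame; stage order is the column order.
#' @export
read_expression <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         colClasses = "character")
  for (j in seq_along(e)[-1]) e[[j]] <- as.numeric(e[[j]])
  if (any(vapply(e[-1], function(v) any(v < 0), logical(1)))) {
    stop("read_expression: negative FPKM")
  }
  e
}

#' Write a genome as FASTA
#' @param genome Named character vector or list of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(dss, path, width = 70)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}
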
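# Synthetic dataset generator with planted ground truth.
#
# The generator lays genes out on a fixed slot grid (16 kb per slot) so that
# promoter/upstream/downstream windows of neighbouring genes never collide and
# a guaranteed-intergenic strip exists in every slot. Peak placement is
# constructive, not rejection-sampled: the planted promoter fraction of each
# peak set is exact. CpG islands are built with an exact count of planted CG
# dinucleotides on a CG-free background, so every island's o/e ratio is known
# in closed form and recorded in the truth record.

SLOT_BP <- 16000
GENE_BODY_OFFSET <- 7000
GENE_BODY_BP <- 4000

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the stated world the generator emulates: a 10% HRunCS cell
#' fraction whose per-cell histone content is 41x that of HRCS (so bulk total
#' : HRCS signal is 5:1), promoter-enriched peak placement, higher CGI o/e at
#' HRCS-target promoters, low methylation at peak-bearing CGIs, and
#' oocyte-high / post-4-cell-suppressed expression for HRCS targets.
#'
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @param n_chromosomes Number of chromosomes; the last one is named `chrX`
#'   and carries genes at `sex_chrom_gene_density` times the autosomal
#'   density.
#' @param chrom_length Chromosome length in bp (multiple of `bin_width`).
#' @param n_genes Number of genes across the genome.
#' @param promoter_peak_fraction Planted fraction of peaks placed in promoter
#'   windows, for each peak set.
#' @param cgi_oe_high_mean,cgi_oe_low_mean Mean target o/e for CGIs at
#'   HRCS-target promoters vs all other promoters.
#' @param hrcs_peak_count,total_peak_count Peak counts per sample.
#' @param hruncs_fraction HRunCS cell fraction f (default 0.10).
#' @param histone_ratio_un_vs_c Per-cell HRunCS:HRCS histone ratio (default
#'   41).
#' @param stages Ordered embryonic stage labels for the expression table.
#' @param fpkm_threshold "Highly expressed" cutoff (default 10).
#' @param bin_width Coverage bin width in bp (default 50).
#' @param background_rate Mean background reads per coverage bin.
#' @param hrcs_promoter_rate,ph_promoter_rate Extra per-bin read rate at
#'   category_H / category_PH promoters in the HRCS track.
#' @param hruncs_promoter_rate Extra rate at all total-target promoters in the
#'   HRunCS track.
#' @param hruncs_peak_halfwidth Half-width in bp of HRunCS promoter signal;
#'   peak breadth of the contaminating population is not pinned down by any
#'   measurement, so it is a parameter (default 750).
#' @param peak_halfwidth Planted peak half-width (default 250; peaks sit
#'   centered on the TSS, inside the +/- 1 kb promoter window).
#' @param cgi_halfwidth CGI half-width around the TSS (default 300).
#' @param cgi_gc GC content of constructed CGIs (default 0.65).
#' @param expression_sdlog Log-normal sdlog for FPKM sampling (default 0.5).
#' @param meth_depth Mean per-site bisulfite read depth (default 20).
#' @param sex_chrom_gene_density Gene (hence CGI/peak) density on `chrX`
#'   relative to autosomes (default 0.5).
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_chromosomes = 4,
                             chrom_length = 1.5e6,
                             n_genes = 120,
                             promoter_peak_fraction = 0.65,
                             cgi_oe_high_mean = 1.2,
                             cgi_oe_low_mean = 0.6,
                             hrcs_peak_count = 40,
                             total_peak_count = 60,
                             hruncs_fraction = 0.10,
                             histone_ratio_un_vs_c = 41,
                             stages = c("oocyte", "zygote", "two_cell",
                                        "four_cell", "eight_cell", "morula",
                                        "ICM"),
                             fpkm_threshold = 10,
                             bin_width = 50,
                             background_rate = 5,
                             hrcs_promoter_rate = 50,
                             ph_promoter_rate = 20,
                             hruncs_promoter_rate = 60,
                             hruncs_peak_halfwidth = 750,
                             peak_halfwidth = 250,
                             cgi_halfwidth = 300,
                             cgi_gc = 0.65,
                             expression_sdlog = 0.5,
                             meth_depth = 20,
                             sex_chrom_gene_density = 0.5) {
  cfg <- as.list(environment())
  props <- c("promoter_peak_fraction", "hruncs_fraction",
             "sex_chrom_gene_density")
  for (p in props) {
    v <- cfg[[p]]
    if (length(v) != 1 || v < 0 || v > 1) {
      stop("generator_config: ", p, " must be a proportion in [0, 1]")
    }
  }
  if (n_chromosomes < 1) stop("generator_config: need >= 1 chromosome")
  if (hrcs_peak_count < 0 || total_peak_count < 0 || n_genes < 1) {
    stop("generator_config: counts must be non-negative (n_genes >= 1)")
  }
  if (chrom_length %% bin_width != 0) {
    stop("generator_config: chrom_length must be a multiple of bin_width")
  }
  if (chrom_length < SLOT_BP) {
    stop("generator_config: chrom_length must be at least ", SLOT_BP, " bp")
  }
  if (histone_ratio_un_vs_c < 0) {
    stop("generator_config: histone_ratio_un_vs_c must be >= 0")
  }
  if (anyDuplicated(stages)) stop("generator_config: stages must be unique")
  structure(cfg, class = "generator_config")
}

# Slot layout: per-chromosome slot starts, interleaved round-robin so genes
# spread evenly across chromosomes; chrX keeps a thinned subset of slots.
slot_layout <- function(cfg) {
  chroms <- if (cfg$n_chromosomes == 1) "chr1" else
    c(paste0("chr", seq_len(cfg$n_chromosomes - 1)), "chrX")
  per <- floor(cfg$chrom_length / SLOT_BP)
  tabs <- lapply(seq_along(chroms), function(i) {
    idx <- seq_len(per)
    if (chroms[i] == "chrX" && cfg$sex_chrom_gene_density < 1) {
      keep <- max(1, round(per * cfg$sex_chrom_gene_density))
      idx <- unique(round(seq(1, per, length.out = keep)))
    }
    data.frame(chrom = chroms[i], slot_start = (idx - 1) * SLOT_BP,
               rank = idx, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, tabs)
  d <- d[order(d$rank, match(d$chrom, chroms)), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "chroms") <- chroms
  d
}

# A CGI sequence with an exact planted count of CG dinucleotides.
# Returns chars plus the closed-form achieved o/e = k * L / (nC * nG).
make_cgi_seq <- function(len, oe_target, gc) {
  n_c <- round(gc * len / 2)
  n_g <- n_c
  k <- max(0L, min(n_c, round(oe_target * n_c * n_g / len)))
  fill <- c(rep("C", n_c - k), rep("G", n_g - k))
  n_at <- len - 2 * k - length(fill)
  fill <- c(fill, rep("A", ceiling(n_at / 2)), rep("T", floor(n_at / 2)))
  fill <- sample(fill)
  fill <- strip_cg(fill)
  cuts <- sort(sample.int(length(fill) + 1, k, replace = TRUE)) - 1
  out <- character(0)
  prev <- 0
  for (cpos in cuts) {
    out <- c(out, fill[seq_len(cpos - prev) + prev], c("C", "G"))
    prev <- cpos
  }
  out <- c(out, if (prev < length(fill)) fill[(prev + 1):length(fill)])
  list(chars = out, oe = k * len / (n_c * n_g), n_cpg = k,
       n_c = n_c, n_g = n_g)
}

# Destroy every CG dinucleotide by swapping it to GC. Matches are disjoint and
# each swap moves a G leftwards, so the pass terminates.
strip_cg <- function(chars) {
  repeat {
    n <- length(chars)
    if (n < 2) return(chars)
    hit <- which(chars[-n] == "C" & chars[-1] == "G")
    if (!length(hit)) return(chars)
    chars[hit] <- "G"
    chars[hit + 1] <- "C"
  }
}

add_poisson_signal <- function(vec, start, end, rate, bw) {
  i0 <- max(0, floor(start / bw))
  i1 <- min(length(vec) - 1, ceiling(end / bw) - 1)
  if (i0 > i1) return(vec)
  idx <- (i0:i1) + 1
  vec[idx] <- vec[idx] + stats::rpois(length(idx), rate)
  vec
}

#' Generate a synthetic dataset with planted truth
#'
#' See [generator_config()] for the stated world. All randomness flows from
#' `config$seed`; two calls with the same config produce identical datasets.
#'
#' @param config A [generator_config()].
#' @return Object of class `sperm_synth`: named genome sequences, gene models,
#'   repeats, annotated CGIs, peak sets (`hrcs`, `total`), coverage tracks
#'   (`hrcs`, `hruncs`, `total`, `input`), per-sample methylation tables,
#'   a gene-by-stage FPKM table, `chrom_sizes`, and a `truth` record
#'   sufficient to score every downstream estimate.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  slots <- slot_layout(cfg)
  chroms <- attr(slots, "chroms")
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, length(chroms)), chroms)

  n_h <- round(cfg$promoter_peak_fraction * cfg$hrcs_peak_count)
  n_tp <- round(cfg$promoter_peak_fraction * cfg$total_peak_count)
  n_prom_pool <- max(n_h, n_tp)
  if (n_prom_pool > cfg$n_genes) {
    stop("generate_dataset: capacity exceeded: ", n_prom_pool,
         " promoter peaks requested but only ", cfg$n_genes, " genes")
  }
  if (cfg$n_genes > nrow(slots)) {
    stop("generate_dataset: capacity exceeded: ", cfg$n_genes,
         " genes but only ", nrow(slots), " slots on the genome")
  }
  n_int_h <- cfg$hrcs_peak_count - n_h
  n_int_t <- cfg$total_peak_count - n_tp
  if (max(n_int_h, n_int_t) > nrow(slots)) {
    stop("generate_dataset: capacity exceeded: ", max(n_int_h, n_int_t),
         " intergenic peaks but only ", nrow(slots), " slots")
  }

  ## ---- gene models ---------------------------------------------------------
  gs <- slots[seq_len(cfg$n_genes), , drop = FALSE]
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  body_lo <- gs$slot_start + GENE_BODY_OFFSET
  body_hi <- body_lo + GENE_BODY_BP
  tss <- ifelse(strand == "+", body_lo, body_hi)
  tes <- ifelse(strand == "+", body_hi, body_lo)
  exon_starts <- sprintf("%d,%d,%d", body_lo, body_lo + 1500, body_lo + 3400)
  exon_ends <- sprintf("%d,%d,%d", body_lo + 400, body_lo + 2200, body_hi)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = gs$chrom, strand = strand, tss = tss, tes = tes,
    exon_starts = exon_starts, exon_ends = exon_ends,
    stringsAsFactors = FALSE)
  validate_genes(genes)

  ## ---- planted categories --------------------------------------------------
  perm <- sample.int(cfg$n_genes)
  h_idx <- perm[seq_len(n_h)]
  tp_idx <- perm[seq_len(n_tp)]
  only_tp <- setdiff(tp_idx, h_idx)
  ph_idx <- only_tp[seq_len(ceiling(length(only_tp) / 2))]
  ts_idx <- setdiff(only_tp, ph_idx)
  category <- rep("none", cfg$n_genes)
  category[h_idx] <- "H"
  category[ph_idx] <- "PH"
  category[ts_idx] <- "TS"

  ## ---- peaks ---------------------------------------------------------------
  hw <- cfg$peak_halfwidth
  prom_peaks <- function(idx, label) {
    if (!length(idx)) return(NULL)
    data.frame(chrom = genes$chrom[idx], start = genes$tss[idx] - hw,
               end = genes$tss[idx] + hw, compartment = "promoter",
               gene = genes$gene_id[idx], stringsAsFactors = FALSE)
  }
  rep_slot <- seq_len(nrow(slots)) %% 3 == 0
  int_peaks <- function(k) {
    if (!k) return(NULL)
    s <- slots$slot_start[seq_len(k)]
    data.frame(chrom = slots$chrom[seq_len(k)], start = s + 500, end = s + 1000,
               compartment = ifelse(rep_slot[seq_len(k)], "intergenic_repeat",
                                    "intergenic_unique"),
               gene = NA_character_, stringsAsFactors = FALSE)
  }
  mk_peakset <- function(prom_idx, n_int, label) {
    d <- rbind(prom_peaks(prom_idx, label), int_peaks(n_int))
    if (is.null(d)) {
      p <- gintervals(character(), numeric(), numeric())
      p$fold_change <- numeric(0); p$fdr <- numeric(0)
      attr(p, "truth_compartment") <- character(0)
      return(p)
    }
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    p <- gintervals(d$chrom, d$start, d$end,
                    name = sprintf("%s_p%04d", label, seq_len(nrow(d))),
                    score = 0)
    p$fold_change <- exp(stats::rnorm(nrow(d), log(10), 0.3))
    p$fdr <- stats::runif(nrow(d), 0, 0.009)
    p$score <- p$fold_change
    attr(p, "truth_compartment") <- d$compartment
    attr(p, "truth_gene") <- d$gene
    p
  }
  peaks <- list(hrcs = mk_peakset(h_idx, n_int_h, "hrcs"),
                total = mk_peakset(tp_idx, n_int_t, "total"))

  ## ---- repeats -------------------------------------------------------------
  rs <- slots$slot_start[rep_slot]
  repeats <- gintervals(slots$chrom[rep_slot], rs + 300, rs + 1200,
                        name = sprintf("rep%04d", seq_len(sum(rep_slot))))

  ## ---- CGIs and genome sequence --------------------------------------------
  oe_target <- ifelse(category == "H",
                      stats::rnorm(cfg$n_genes, cfg$cgi_oe_high_mean, 0.08),
                      stats::rnorm(cfg$n_genes, cfg$cgi_oe_low_mean, 0.08))
  oe_target <- pmin(pmax(oe_target, 0.2), 1.9)
  cgi_len <- 2 * cfg$cgi_halfwidth

  genome_chars <- lapply(chroms, function(ch) {
    strip_cg(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)))
  })
  names(genome_chars) <- chroms

  cgi_start <- genes$tss - cfg$cgi_halfwidth
  oe_achieved <- n_cpg <- n_c <- n_g <- numeric(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    s <- make_cgi_seq(cgi_len, oe_target[i], cfg$cgi_gc)
    genome_chars[[genes$chrom[i]]][cgi_start[i] + seq_len(cgi_len)] <- s$chars
    oe_achieved[i] <- s$oe; n_cpg[i] <- s$n_cpg
    n_c[i] <- s$n_c; n_g[i] <- s$n_g
  }
  genome <- vapply(genome_chars, paste0, character(1), collapse = "")

  cgis <- gintervals(genes$chrom, cgi_start, cgi_start + cgi_len,
                     name = sprintf("cgi_%s", genes$gene_id),
                     score = oe_achieved)
  cgis$n_cpg <- n_cpg; cgis$n_c <- n_c; cgis$n_g <- n_g
  cgis$length <- cgi_len; cgis$oe <- oe_achieved
  cgis <- sort_intervals(cgis)

  ## ---- coverage tracks -----------------------------------------------------
  bw <- cfg$bin_width
  nb <- cfg$chrom_length / bw
  blank <- function() {
    stats::setNames(lapply(chroms, function(ch) numeric(nb)), chroms)
  }
  pois_bg <- function() {
    stats::setNames(lapply(chroms, function(ch)
      as.numeric(stats::rpois(nb, cfg$background_rate))), chroms)
  }
  hrcs_counts <- pois_bg()
  for (i in h_idx) {
    hrcs_counts[[genes$chrom[i]]] <- add_poisson_signal(
      hrcs_counts[[genes$chrom[i]]], genes$tss[i] - 500, genes$tss[i] + 500,
      cfg$hrcs_promoter_rate, bw)
  }
  for (i in ph_idx) {
    hrcs_counts[[genes$chrom[i]]] <- add_poisson_signal(
      hrcs_counts[[genes$chrom[i]]], genes$tss[i] - 500, genes$tss[i] + 500,
      cfg$ph_promoter_rate, bw)
  }
  hp <- peaks$hrcs[attr(peaks$hrcs, "truth_compartment") != "promoter", ,
                   drop = FALSE]
  for (i in seq_len(nrow(hp))) {
    hrcs_counts[[hp$chrom[i]]] <- add_poisson_signal(
      hrcs_counts[[hp$chrom[i]]], hp$start[i], hp$end[i],
      cfg$hrcs_promoter_rate, bw)
  }
  hruncs_counts <- pois_bg()
  for (i in tp_idx) {
    hruncs_counts[[genes$chrom[i]]] <- add_poisson_signal(
      hruncs_counts[[genes$chrom[i]]],
      genes$tss[i] - cfg$hruncs_peak_halfwidth,
      genes$tss[i] + cfg$hruncs_peak_halfwidth,
      cfg$hruncs_promoter_rate, bw)
  }
  tp <- peaks$total[attr(peaks$total, "truth_compartment") != "promoter", ,
                    drop = FALSE]
  for (i in seq_len(nrow(tp))) {
    hruncs_counts[[tp$chrom[i]]] <- add_poisson_signal(
      hruncs_counts[[tp$chrom[i]]], tp$start[i], tp$end[i],
      cfg$hruncs_promoter_rate, bw)
  }
  hrcs_cov <- coverage_track(hrcs_counts, bw)
  hruncs_cov <- coverage_track(hruncs_counts, bw)
  spec <- mixture_spec(f = cfg$hruncs_fraction,
                       h_un_over_h_c = cfg$histone_ratio_un_vs_c)
  total_cov <- mix_total_sperm(hrcs_cov, hruncs_cov, spec)
  input_cov <- coverage_track(pois_bg(), bw)

  ## ---- methylation ---------------------------------------------------------
  peak_bearing <- seq_len(cfg$n_genes) %in% union(tp_idx, h_idx)
  meth <- list(hrcs = NULL, total = NULL)
  rows <- list()
  ord <- order(genes$chrom, genes$tss)
  for (i in ord) {
    sub <- substr(genome[[genes$chrom[i]]], cgi_start[i] + 1,
                  cgi_start[i] + cgi_len)
    mpos <- gregexpr("CG", sub, fixed = TRUE)[[1]]
    if (mpos[1] == -1) next
    pos0 <- cgi_start[i] + mpos - 1
    lev <- if (peak_bearing[i]) stats::rbeta(length(pos0), 0.5, 5)
           else stats::rbeta(length(pos0), 5, 1.5)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = genes$chrom[i], pos0 = as.numeric(pos0), level = lev,
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  for (sm in names(meth)) {
    tot <- stats::rpois(nrow(sites), cfg$meth_depth) + 1
    m <- stats::rbinom(nrow(sites), tot, sites$level)
    meth[[sm]] <- data.frame(chrom = sites$chrom, pos0 = sites$pos0,
                             methylated = m, total = tot,
                             stringsAsFactors = FALSE)
  }

  ## ---- expression ----------------------------------------------------------
  S <- length(cfg$stages)
  m_h <- rep(1, S); m_h[seq_len(min(2, S))] <- 30
  if (S >= 3) m_h[3] <- 15
  if (S >= 4) m_h[4] <- 5
  m_ts <- rep(20, S); m_ts[1] <- 30; if (S >= 2) m_ts[2] <- 25
  m_none <- rep(8, S)
  expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (j in seq_len(S)) {
    mu <- ifelse(category %in% c("H", "PH"), m_h[j],
          ifelse(category == "TS", m_ts[j], m_none[j]))
    expr[[cfg$stages[j]]] <- stats::rlnorm(cfg$n_genes, log(mu),
                                           cfg$expression_sdlog)
  }

  ## ---- truth ---------------------------------------------------------------
  truth <- list(
    seed = cfg$seed,
    genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       category = category,
                       oe_target = oe_target, oe_achieved = oe_achieved,
                       has_hrcs_peak = seq_len(cfg$n_genes) %in% h_idx,
                       has_total_peak = seq_len(cfg$n_genes) %in% tp_idx,
                       peak_bearing_cgi = peak_bearing,
                       stringsAsFactors = FALSE),
    peaks = lapply(peaks, function(p) {
      data.frame(name = p$name, compartment = attr(p, "truth_compartment"),
                 stringsAsFactors = FALSE)
    }),
    n_promoter_peaks = list(hrcs = n_h, total = n_tp),
    promoter_fraction = list(
      hrcs = if (cfg$hrcs_peak_count > 0) n_h / cfg$hrcs_peak_count else NA,
      total = if (cfg$total_peak_count > 0) n_tp / cfg$total_peak_count else NA),
    mixture = list(f = cfg$hruncs_fraction,
                   h_un_over_h_c = cfg$histone_ratio_un_vs_c,
                   expected_bulk_ratio = forward_ratio(
                     cfg$hruncs_fraction, cfg$histone_ratio_un_vs_c)),
    stage_means = list(H_PH = m_h, TS = m_ts, none = m_none))

  structure(list(config = cfg, genome = genome, genes = genes,
                 repeats = repeats, cgis = cgis, peaks = peaks,
                 coverage = list(hrcs = hrcs_cov, hruncs = hruncs_cov,
                                 total = total_cov, input = input_cov),
                 methylation = meth, expression = expr,
                 chrom_sizes = chrom_sizes, truth = truth),
            class = "sperm_synth")
}

#' @export
print.sperm_synth <- function(x, ...) {
  cat("sperm_synth dataset: ", length(x$genome), " chromosome(s) x ",
      format(x$config$chrom_length, big.mark = ","), " bp, ",
      nrow(x$genes), " genes, ",
      nrow(x$peaks$hrcs), " HRCS / ", nrow(x$peaks$total),
      " total-sperm peaks\n", sep = "")
  cat("planted categories:",
      paste(names(table(x$truth$genes$category)),
            table(x$truth$genes$category), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in plain-text formats
#'
#' FASTA genome, refFlat-style gene TSV, BED6 repeats/peaks, BED6+3 CGIs,
#' bedGraph coverage with depth sidecars, per-sample methylation TSVs, FPKM
#' TSV and a JSON truth record. Output is byte-deterministic for a fixed
#' dataset.
#'
#' @param ds A [generate_dataset()] result.
#' @param outdir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  stopifnot(inherits(ds, "sperm_synth"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  files <- c(genome = p("genome.fa"), genes = p("genes.tsv"),
             repeats = p("repeats.bed"), cgis = p("cgis.bed"),
             expression = p("expression.tsv"), truth = p("truth.json"))
  write_genome_fasta(ds$genome, files["genome"])
  write_gene_table(ds$genes, files["genes"])
  write_bed(ds$repeats, files["repeats"])
  cgi_bed <- ds$cgis
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t.\t%d\t%d\t%s",
                   cgi_bed$chrom, format_coord(cgi_bed$start),
                   format_coord(cgi_bed$end), cgi_bed$name,
                   format_num(cgi_bed$oe), cgi_bed$n_cpg,
                   cgi_bed$n_c + cgi_bed$n_g, format_num(cgi_bed$oe))
  writeLines(lines, files["cgis"])
  for (sm in names(ds$peaks)) {
    f <- p(sprintf("peaks_%s.bed", sm))
    write_bed(ds$peaks[[sm]], f)
    files[paste0("peaks_", sm)] <- f
  }
  for (sm in names(ds$coverage)) {
    f <- p(sprintf("coverage_%s.bedGraph", sm))
    write_bedgraph(ds$coverage[[sm]], f, sample = sm)
    files[paste0("coverage_", sm)] <- f
  }
  for (sm in names(ds$methylation)) {
    f <- p(sprintf("methylation_%s.tsv", sm))
    write_methylation(ds$methylation[[sm]], f)
    files[paste0("methylation_", sm)] <- f
  }
  write_expression(ds$expression, files["expression"])
  jsonlite::write_json(ds$truth, files["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
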
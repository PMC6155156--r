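# Independent oracles. Deliberately naive: they never share code with the
# implementation paths they check.

# O(|a| * |b|) all-pairs overlap count.
brute_overlap_count <- function(a, b) {
  n_hit <- 0L
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit <- TRUE
        break
      }
    }
    if (hit) n_hit <- n_hit + 1L
  }
  list(n_a_hit = n_hit, fraction = n_hit / nrow(a))
}

# Dinucleotide-walking o/e counter.
brute_oe <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  n_c <- 0L; n_g <- 0L; len <- 0L; n_cpg <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] != "N") len <- len + 1L
    if (chars[i] == "C") n_c <- n_c + 1L
    if (chars[i] == "G") n_g <- n_g + 1L
    if (i > 1 && chars[i - 1] == "C" && chars[i] == "G") n_cpg <- n_cpg + 1L
  }
  if (n_c * n_g == 0) return(NA_real_)
  n_cpg * len / (n_c * n_g)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all C(n+m, n)
# rank assignments (untied data only).
wilcox_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  all_r <- seq_len(n + m)
  u_all <- apply(combos, 2, function(ix) sum(all_r[ix]) - n * (n + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_len, n, replace = TRUE))
}

random_gene_set <- function(n, chrom_sizes, seed_body_min = 2000,
                            seed_body_max = 9000) {
  chroms <- names(chrom_sizes)
  ch <- sample(chroms, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body_len <- sample(seed_body_min:seed_body_max, n, replace = TRUE)
  lo <- vapply(seq_len(n), function(i) {
    sample.int(chrom_sizes[[ch[i]]] - body_len[i] - 12000, 1) + 6000
  }, numeric(1))
  hi <- lo + body_len
  ex1 <- sprintf("%d", lo)
  exe1 <- sprintf("%d", lo + pmax(200, body_len %/% 4))
  data.frame(gene_id = sprintf("rg%03d", seq_len(n)), chrom = ch,
             strand = strand,
             tss = ifelse(strand == "+", lo, hi),
             tes = ifelse(strand == "+", hi, lo),
             exon_starts = ex1, exon_ends = exe1,
             stringsAsFactors = FALSE)
}
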
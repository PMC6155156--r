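toy_sizes <- c(chr1 = 60000, chr2 = 60000)

test_that("strand-aware windows follow the definitions", {
  g <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                  strand = c("+", "-"),
                  tss = c(10000, 50000), tes = c(14000, 46000),
                  exon_starts = c("10000", "46000"),
                  exon_ends = c("10400", "46400"),
                  stringsAsFactors = FALSE)
  ann <- build_annotation(g, gintervals(character(), numeric(), numeric()),
                          toy_sizes)
  prom <- ann$classes$promoter
  expect_true(any(prom$start == 9000 & prom$end == 11000))
  expect_true(any(prom$start == 49000 & prom$end == 51000))
  up <- ann$classes$upstream
  expect_true(any(up$start == 5000 & up$end == 9000))    # + strand
  expect_true(any(up$start == 51000 & up$end == 55000))  # - strand reflection
  down <- ann$classes$downstream
  expect_true(any(down$start == 14000 & down$end == 19000))
  expect_true(any(down$start == 41000 & down$end == 46000))
})

test_that("precedence matches a per-base brute-force oracle", {
  # two overlapping genes: B's promoter punches into A's intron, etc.
  g <- data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = "+",
                  tss = c(10000, 16000), tes = c(30000, 22000),
                  exon_starts = c("10000,20000", "16000"),
                  exon_ends = c("12000,21000", "17000"),
                  stringsAsFactors = FALSE)
  reps <- gintervals("chr1", 40000, 45000)
  ann <- build_annotation(g, reps, c(chr1 = 60000))
  # oracle: classify each probed base independently from the definitions
  probe <- c(9500, 10500, 13000, 15500, 16500, 20500, 25000, 31000, 33000,
             41000, 50000)
  oracle <- function(pos) {
    in_any <- function(lo, hi) pos >= lo & pos < hi
    prom <- in_any(9000, 11000) | in_any(15000, 17000)
    exon <- in_any(10000, 12000) | in_any(20000, 21000) | in_any(16000, 17000)
    body <- in_any(10000, 30000) | in_any(16000, 22000)
    intron <- body & !exon
    upst <- in_any(5000, 9000) | in_any(11000, 15000)
    down <- in_any(30000, 35000) | in_any(22000, 27000)
    if (prom) "promoter" else if (exon) "exon" else if (intron) "intron"
    else if (upst) "upstream" else if (down) "downstream"
    else if (in_any(40000, 45000)) "intergenic_repeat" else "intergenic_unique"
  }
  pk <- gintervals("chr1", probe, probe + 1)
  tab_cls <- vapply(probe, oracle, character(1))
  got <- peak_compartment_table(pk, ann)
  want <- table(factor(tab_cls, levels = got$class))
  expect_equal(got$count, as.integer(want))
})

test_that("annotation partitions the genome on 50 random toy gene sets", {
  set.seed(404)
  for (rep in 1:50) {
    g <- random_gene_set(sample(3:8, 1), toy_sizes)
    reps <- random_intervals(sample(0:5, 1), names(toy_sizes),
                             max_pos = 55000, max_len = 2000)
    ann <- build_annotation(g, reps, toy_sizes)
    part <- check_partition(ann)
    expect_true(part$ok)
    expect_equal(part$total_class_bp, sum(toy_sizes))
    expect_equal(part$max_pairwise_overlap_bp, 0)
  }
})

test_that("peak assignment is invariant under row permutation", {
  ds <- small_dataset()
  ann <- build_annotation(ds$genes, ds$repeats, ds$chrom_sizes)
  pk <- ds$peaks$total
  set.seed(1)
  tab1 <- peak_compartment_table(pk, ann)
  tab2 <- peak_compartment_table(pk[sample(nrow(pk)), ], ann)
  expect_equal(tab1, tab2)
})

test_that("windows clip at chromosome bounds; unknown chromosomes error", {
  g <- data.frame(gene_id = "edge", chrom = "chr1", strand = "+",
                  tss = 3000, tes = 7000, exon_starts = "3000",
                  exon_ends = "3400", stringsAsFactors = FALSE)
  ann <- build_annotation(g, gintervals(character(), numeric(), numeric()),
                          c(chr1 = 9000))
  expect_true(check_partition(ann)$ok)  # upstream/downstream clipped, no gap
  g$chrom <- "chrZ"
  expect_error(
    build_annotation(g, gintervals(character(), numeric(), numeric()),
                     c(chr1 = 9000)),
    "unknown chromosome")
})

test_that("uniform peaks give enrichment ~1 in every large class", {
  set.seed(505)
  g <- random_gene_set(6, toy_sizes)
  ann <- build_annotation(g, gintervals("chr1", 0, 30000), toy_sizes)
  pos <- sample.int(sum(toy_sizes) - 1, 4000, replace = TRUE) - 1
  pk <- gintervals(ifelse(pos < toy_sizes[1], "chr1", "chr2"),
                   pos %% toy_sizes[1], pos %% toy_sizes[1] + 1)
  tab <- peak_compartment_table(pk, ann)
  big <- tab$genome_fraction > 0.05
  expect_true(all(abs(tab$enrichment[big] - 1) < 0.15))
})

test_that("planted promoter fraction is recovered from the truth world", {
  ds <- small_dataset()
  ann <- build_annotation(ds$genes, ds$repeats, ds$chrom_sizes)
  tab <- peak_compartment_table(ds$peaks$total, ann)
  expect_equal(tab$fraction[tab$class == "promoter"],
               ds$truth$promoter_fraction$total, tolerance = 1e-12)
})
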
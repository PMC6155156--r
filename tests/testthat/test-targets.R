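toy_genes <- function() {
  data.frame(gene_id = c("A", "B", "C", "D"), chrom = "chr1", strand = "+",
             tss = c(10000, 12500, 40000, 70000),
             tes = c(20000, 22000, 50000, 80000),
             exon_starts = NA_character_, exon_ends = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("target genes are promoter hits only, deduplicated", {
  g <- toy_genes()
  # one peak spanning the adjacent promoters of A and B hits both
  pk <- gintervals("chr1", c(10900, 39500, 75000), c(11600, 40100, 75200))
  expect_equal(peaks_to_genes(pk, g), c("A", "B", "C"))  # D's peak is exonic
  expect_equal(peaks_to_genes(pk[0, ], g), character(0))
})

test_that("overlap percentages use nearest-integer rounding on printed pairs", {
  expect_identical(overlap_percent(966, 1320), 73L)
  expect_identical(overlap_percent(905, 911), 99L)
  expect_identical(overlap_percent(686, 911), 75L)
  expect_error(overlap_percent(1, 0), "positive")
})

test_that("overlap_summary reports both levels for each ordered pair", {
  g <- toy_genes()
  pk1 <- gintervals("chr1", c(9500, 39500), c(10500, 40500))   # A, C proms
  pk2 <- gintervals("chr1", c(10400, 69500), c(11000, 70500))  # A, D proms
  s <- overlap_summary(list(x = pk1, y = pk2), g)
  xp <- s[s$sample_a == "x" & s$level == "peak", ]
  expect_equal(xp$n, 2); expect_equal(xp$n_hit, 1); expect_equal(xp$percent, 50L)
  xg <- s[s$sample_a == "x" & s$level == "gene", ]
  expect_equal(xg$n, 2)        # targets {A, C}
  expect_equal(xg$n_hit, 1)    # shared {A}
  # disjoint sets give 0 at both levels
  s0 <- overlap_summary(list(x = pk1, y = gintervals("chr1", 1, 2)), g)
  expect_true(all(s0$n_hit == 0))
  expect_error(overlap_summary(list(x = pk1, y = pk1[0, ]), g), "empty")
})

test_that("categorization follows the H / PH / TS rules", {
  g <- toy_genes()
  # uniform HRCS coverage, empty HRCS peak set: everything total becomes TS
  cov <- coverage_track(list(chr1 = rep(5, 2000)), 50)
  pk_total <- gintervals("chr1", c(9500, 39500, 69500),
                         c(10500, 40500, 70500))
  gt <- peaks_to_genes(pk_total, g)
  cat0 <- categorize_targets(gt, character(0), cov, pk_total, g)
  expect_true(all(cat0$category == "TS"))
  # an HRCS peak makes a gene H regardless of signal
  gh <- peaks_to_genes(gintervals("chr1", 9500, 10500), g)
  cat1 <- categorize_targets(gt, gh, cov, pk_total, g)
  expect_equal(cat1$category[cat1$gene_id == "A"], "H")
  # strong HRCS signal without an HRCS peak makes PH
  v <- rep(5, 2000); v[(39500 %/% 50):(40500 %/% 50) + 1] <- 50
  cov2 <- coverage_track(list(chr1 = v), 50)
  cat2 <- categorize_targets(gt, gh, cov2, pk_total, g)
  expect_equal(cat2$category[cat2$gene_id == "C"], "PH")
  expect_equal(cat2$category[cat2$gene_id == "D"], "TS")
  expect_error(categorize_targets(gt, gh, cov, pk_total, g, k_background = 0),
               "k_background")
})

test_that("categories are disjoint, exhaustive and monotone in k", {
  ds <- small_dataset()
  gt <- peaks_to_genes(ds$peaks$total, ds$genes)
  gh <- peaks_to_genes(ds$peaks$hrcs, ds$genes)
  cat2 <- categorize_targets(gt, gh, ds$coverage$hrcs, ds$peaks$total,
                             ds$genes, k_background = 2)
  expect_setequal(cat2$gene_id, union(gt, gh))
  expect_true(all(cat2$category %in% c("H", "PH", "TS")))
  expect_true(all(cat2$category[cat2$in_hrcs] == "H"))
  for (k in c(3, 5, 10)) {
    catk <- categorize_targets(gt, gh, ds$coverage$hrcs, ds$peaks$total,
                               ds$genes, k_background = k)
    # larger k never moves a gene from TS to PH
    was_ts <- cat2$gene_id[cat2$category == "TS"]
    expect_true(all(catk$category[catk$gene_id %in% was_ts] == "TS"))
  }
})

test_that("planted categories are recovered on the small world", {
  ds <- small_dataset()
  gt <- peaks_to_genes(ds$peaks$total, ds$genes)
  gh <- peaks_to_genes(ds$peaks$hrcs, ds$genes)
  catalog <- categorize_targets(gt, gh, ds$coverage$hrcs, ds$peaks$total,
                                ds$genes)
  planted <- stats::setNames(ds$truth$genes$category, ds$truth$genes$gene_id)
  expect_gte(mean(catalog$category == planted[catalog$gene_id]), 0.95)
})
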
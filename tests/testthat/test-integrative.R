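mk_meth <- function(chrom, pos0, level, total = 10) {
  data.frame(chrom = chrom, pos0 = pos0,
             methylated = round(level * total), total = total,
             stringsAsFactors = FALSE)
}

test_that("region methylation averages qualifying sites, unweighted", {
  reg <- gintervals("chr1", 100, 200)
  expect_equal(as.numeric(region_methylation(
    mk_meth("chr1", 150, 0.8), reg)), 0.8)
  m <- mk_meth("chr1", c(110, 120, 130), c(1, 0.5, 0))
  expect_equal(as.numeric(region_methylation(m, reg)), 0.5)
  # min_coverage excludes a shallow site; mean over the rest only
  m4 <- data.frame(chrom = "chr1", pos0 = c(110, 120, 130, 140),
                   methylated = c(3, 10, 0, 5), total = c(3, 10, 10, 10))
  expect_equal(as.numeric(region_methylation(m4, reg, min_coverage = 5)),
               mean(c(1.0, 0.0, 0.5)))
  expect_error(region_methylation(m4, reg, min_coverage = 0), "min_coverage")
})

test_that("regions without qualifying sites are missing and counted", {
  reg <- gintervals("chr1", c(0, 1000), c(100, 1100))
  m <- mk_meth("chr1", 50, 0.4)
  lev <- region_methylation(m, reg)
  expect_equal(as.numeric(lev), c(0.4, NA))
  expect_equal(attr(lev, "n_missing"), 1L)
})

test_that("region methylation is permutation-invariant and within [0,1]", {
  set.seed(909)
  m <- data.frame(chrom = "chr1", pos0 = sample.int(5000, 200) - 1,
                  total = sample(1:30, 200, TRUE))
  m$methylated <- rbinom(200, m$total, 0.3)
  reg <- random_intervals(20, "chr1", max_pos = 4500, max_len = 800)
  l1 <- region_methylation(m, reg, min_coverage = 3)
  l2 <- region_methylation(m[sample(nrow(m)), ], reg, min_coverage = 3)
  expect_equal(l1, l2)
  expect_true(all(is.na(l1) | (l1 >= 0 & l1 <= 1)))
})

test_that("peak-bearing CGIs are planted hypomethylated", {
  ds <- small_dataset()
  lev <- region_methylation(ds$methylation$hrcs, ds$cgis)
  bearing <- ds$truth$genes$peak_bearing_cgi[
    match(sub("^cgi_", "", ds$cgis$name), ds$truth$genes$gene_id)]
  expect_lt(mean(lev[bearing], na.rm = TRUE) + 0.3,
            mean(lev[!bearing], na.rm = TRUE))
})

test_that("Pearson correlation matches the direct covariance formula", {
  expect_equal(methylation_correlation(1:10 / 10, 1:10 / 10)$r, 1.0)
  expect_equal(methylation_correlation(1:10 / 10, 1 - 1:10 / 10)$r, -1.0)
  set.seed(910)
  x <- runif(50); y <- runif(50)
  x[c(3, 7)] <- NA
  ok <- !is.na(x)
  direct <- sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok]))) /
    sqrt(sum((x[ok] - mean(x[ok]))^2) * sum((y[ok] - mean(y[ok]))^2))
  mc <- methylation_correlation(x, y)
  expect_equal(mc$r, direct, tolerance = 1e-12)
  expect_equal(mc$n, 48)
  expect_error(methylation_correlation(c(1, 2), c(1, 2)), "pairs")
  expect_error(methylation_correlation(1:5, 1:4), "paired")
})

test_that("expression dynamics: strict threshold, conditioning, hand count", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d"),
                     oocyte = c(20, 20, 20, 20),
                     four_cell = c(12, 9, 30, 10))
  cats <- stats::setNames(rep("H", 4), expr$gene_id)
  dyn <- expression_dynamics(expr, cats, threshold = 10,
                             condition_stage = "oocyte")
  h4 <- dyn$fraction[dyn$category == "H" & dyn$stage == "four_cell"]
  expect_equal(h4, 2 / 4)  # 12 and 30 pass; 10 fails the strict inequality
  # all-zero FPKM: conditioned universe empty, reported missing
  expr0 <- expr; expr0$oocyte <- 0; expr0$four_cell <- 0
  dyn0 <- expression_dynamics(expr0, cats)
  expect_true(all(is.na(dyn0$fraction)))
  expect_true(all(dyn0$n == 0))
  expect_error(expression_dynamics(expr, cats, condition_stage = "icm"),
               "not in table")
})

test_that("with a fixed universe, raising the threshold never raises fractions", {
  ds <- small_dataset()
  cats <- stats::setNames(ds$truth$genes$category, ds$truth$genes$gene_id)
  cats <- cats[cats != "none"]
  d10 <- expression_dynamics(ds$expression, cats, threshold = 10,
                             condition_universe = FALSE)
  d20 <- expression_dynamics(ds$expression, cats, threshold = 20,
                             condition_universe = FALSE)
  expect_true(all(d20$fraction <= d10$fraction + 1e-12, na.rm = TRUE))
  expect_true(all(d10$fraction >= 0 & d10$fraction <= 1, na.rm = TRUE))
})

test_that("planted suppression: H collapses after the 4-cell stage", {
  ds <- small_dataset()
  cats <- stats::setNames(ds$truth$genes$category, ds$truth$genes$gene_id)
  cats <- cats[cats != "none"]
  dyn <- expression_dynamics(ds$expression, cats, threshold = 10,
                             condition_stage = "oocyte")
  f <- function(cat, st) dyn$fraction[dyn$category == cat & dyn$stage == st]
  expect_gt(f("H", "oocyte"), 0.95)      # conditioned on oocyte expression
  expect_lt(f("H", "ICM"), 0.1)          # planted post-ZGA suppression
  expect_gt(f("all", "ICM"), f("H", "ICM") + 0.1)  # all genes decline less
})
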
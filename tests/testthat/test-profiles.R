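flat_track <- function(value = 2, n = 400, bw = 50, total = 1e6) {
  coverage_track(list(chr1 = rep(value, n)), bw, total_mapped_reads = total)
}

test_that("flat coverage gives a constant matrix with RPM normalization", {
  tr <- flat_track(value = 7, total = 1e6)
  anchors <- data.frame(chrom = "chr1", pos = c(5000, 9000),
                        strand = c("+", "-"))
  m <- build_tss_matrix(tr, anchors, window = 3000, bin_width = 50)
  expect_equal(dim(m$values), c(2, 60))
  expect_true(all(m$values == 7))  # 7 reads/bin * 1e6 / 1e6 depth
  expect_false(any(m$edge_flag))
})

test_that("minus-strand rows are flipped so column 1 is 5'-most", {
  v <- rep(0, 400); v[1001 / 50 + 1] <- 0  # explicit zero base
  v[(1000 %/% 50) + 1] <- 1                # one read in [1000, 1050)
  tr <- coverage_track(list(chr1 = v), 50, total_mapped_reads = 1e6)
  anchors <- data.frame(chrom = "chr1", pos = 1000, strand = "-")
  m <- build_tss_matrix(tr, anchors, window = 200, bin_width = 50)
  # genomically just right of the anchor = upstream of a minus-strand TSS;
  # after the flip it sits immediately left of center: column n/2 (1-based)
  expect_equal(which(m$values[1, ] != 0), 200 / 50 / 2)
  m_plus <- build_tss_matrix(tr, transform(anchors, strand = "+"),
                             window = 200, bin_width = 50)
  expect_equal(m_plus$values[1, ], rev(m$values[1, ]))  # flip is a reversal
})

test_that("strand flip is an involution", {
  set.seed(808)
  tr <- coverage_track(list(chr1 = as.numeric(rpois(400, 3))), 50)
  a_minus <- data.frame(chrom = "chr1", pos = 6000, strand = "-")
  m1 <- build_tss_matrix(tr, a_minus, window = 1000, bin_width = 50)
  expect_equal(rev(rev(m1$values[1, ])), m1$values[1, ])
  a_plus <- transform(a_minus, strand = "+")
  mp <- build_tss_matrix(tr, a_plus, window = 1000, bin_width = 50)
  expect_equal(m1$values[1, ], rev(mp$values[1, ]))
})

test_that("conservation and normalization invariance hold on random input", {
  set.seed(809)
  counts <- as.numeric(rpois(500, 4))
  tr <- coverage_track(list(chr1 = counts), 50, total_mapped_reads = 2e5)
  anchors <- data.frame(chrom = "chr1",
                        pos = sample(seq(2000, 20000, 50), 15),
                        strand = sample(c("+", "-"), 15, TRUE))
  m <- build_tss_matrix(tr, anchors, window = 3000, bin_width = 50)
  # conservation: matrix total equals RPM-normalized raw counts in windows
  raw <- sum(vapply(seq_len(nrow(anchors)), function(i) {
    w0 <- anchors$pos[i] - 1500
    sum(counts[(w0 / 50 + 1):(w0 / 50 + 60)])
  }, numeric(1)))
  expect_equal(sum(m$values), raw * 1e6 / 2e5, tolerance = 1e-9)
  # doubling counts and depth together changes nothing
  tr2 <- coverage_track(list(chr1 = counts * 2), 50, total_mapped_reads = 4e5)
  m2 <- build_tss_matrix(tr2, anchors, window = 3000, bin_width = 50)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
})

test_that("edge anchors are zero-padded and flagged, not dropped", {
  tr <- flat_track(value = 1, n = 100)
  anchors <- data.frame(chrom = "chr1", pos = c(200, 2500), strand = "+",
                        name = c("edge", "mid"))
  m <- build_tss_matrix(tr, anchors, window = 3000, bin_width = 50)
  expect_equal(unname(m$edge_flag), c(TRUE, FALSE))
  expect_equal(nrow(m$values), 2)
  expect_true(all(m$values["edge", 1:20] == 0))  # bins before position 0
  expect_error(build_tss_matrix(tr, anchors, window = 3000, bin_width = 70),
               "divisible")
})

test_that("profile curve is the column mean; single row is the identity", {
  tr <- flat_track()
  anchors <- data.frame(chrom = "chr1", pos = c(5000, 9000), strand = "+")
  m <- build_tss_matrix(tr, anchors, window = 300, bin_width = 50)
  m$values[1, ] <- c(0, 2, 4, 6, 8, 10)
  m$values[2, ] <- 2
  expect_equal(profile_curve(m)$mean_rpm, c(1, 2, 3, 4, 5, 6))
  m$values <- m$values[1, , drop = FALSE]
  expect_equal(profile_curve(m)$mean_rpm, c(0, 2, 4, 6, 8, 10))
  m$values <- m$values[0, , drop = FALSE]
  expect_error(profile_curve(m), "empty")
})

test_that("planted promoter signal peaks at the center for HRCS targets", {
  ds <- small_dataset()
  tr_genes <- ds$truth$genes
  h_ids <- tr_genes$gene_id[tr_genes$category == "H"]
  anchors <- data.frame(chrom = ds$genes$chrom, pos = ds$genes$tss,
                        strand = ds$genes$strand, name = ds$genes$gene_id)
  m_h <- build_tss_matrix(ds$coverage$hrcs,
                          anchors[anchors$name %in% h_ids, ])
  curve <- profile_curve(m_h)
  center <- which(curve$offset_bp == 0)
  expect_gt(curve$mean_rpm[center], 3 * curve$mean_rpm[1])
  none_ids <- tr_genes$gene_id[tr_genes$category == "none"]
  m_0 <- build_tss_matrix(ds$coverage$hrcs,
                          anchors[anchors$name %in% none_ids, ])
  c0 <- profile_curve(m_0)
  expect_lt(max(c0$mean_rpm) / min(c0$mean_rpm), 2)
})

test_that("heatmap ordering matches a brute-force sort and round-trips", {
  set.seed(810)
  tr <- coverage_track(list(chr1 = as.numeric(rpois(500, 6))), 50)
  anchors <- data.frame(chrom = "chr1", pos = seq(3000, 12000, 1000),
                        strand = "+",
                        name = sprintf("a%02d", 1:10))
  m <- build_tss_matrix(tr, anchors, window = 1000, bin_width = 50)
  hm <- export_heatmap_matrix(m, "mean_desc")
  mu <- rowMeans(m$values)
  want <- rownames(m$values)[order(-mu, rownames(m$values))]
  expect_equal(rownames(hm), want)
  given <- sample(rownames(m$values))
  hm2 <- export_heatmap_matrix(m, "given", given = given)
  expect_equal(rownames(hm2), given)
  expect_error(export_heatmap_matrix(m, "given", given = given[-1]),
               "row names")
})
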
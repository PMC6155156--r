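test_that("identical seeds give identical datasets and identical files", {
  ds1 <- generate_dataset(tiny_config(seed = 5))
  ds2 <- generate_dataset(tiny_config(seed = 5))
  expect_identical(ds1$genome, ds2$genome)
  expect_identical(ds1$genes, ds2$genes)
  expect_identical(ds1$peaks, ds2$peaks)
  expect_identical(ds1$coverage, ds2$coverage)
  expect_identical(ds1$expression, ds2$expression)
  expect_identical(ds1$truth, ds2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_dataset(ds1, d1); f2 <- write_dataset(ds2, d2)
  expect_identical(unname(tools::md5sum(unlist(f1))),
                   unname(tools::md5sum(unlist(f2))))
  ds3 <- generate_dataset(tiny_config(seed = 6))
  expect_false(identical(ds1$genome, ds3$genome))
})

test_that("planted promoter placement is exact: 26 of 40 peaks at 0.65", {
  cfg <- generator_config(seed = 1, n_genes = 50,
                          promoter_peak_fraction = 0.65, hrcs_peak_count = 40)
  ds <- generate_dataset(cfg)
  planted <- ds$truth$peaks$hrcs$compartment
  expect_equal(sum(planted == "promoter"), 26L)
  expect_equal(length(planted), 40L)
  # and the planted label is true: those peaks sit inside promoter windows
  prom <- promoter_windows(ds$genes)
  hit <- overlaps_any(ds$peaks$hrcs, prom)
  expect_equal(sum(hit[planted == "promoter"]), 26L)
})

test_that("promoter fraction boundary cases", {
  ds <- generate_dataset(generator_config(seed = 2, n_chromosomes = 2,
                                          chrom_length = 256000, n_genes = 12,
                                          promoter_peak_fraction = 1,
                                          hrcs_peak_count = 10,
                                          total_peak_count = 12))
  expect_true(all(ds$truth$peaks$hrcs$compartment == "promoter"))
  expect_true(all(ds$truth$peaks$total$compartment == "promoter"))
})

test_that("configs exceeding genome capacity raise explicit errors", {
  expect_error(generate_dataset(
    generator_config(seed = 1, n_genes = 5, total_peak_count = 60)),
    "capacity")
  expect_error(generate_dataset(
    generator_config(seed = 1, n_chromosomes = 1, chrom_length = 64000,
                     n_genes = 50)),
    "capacity")
  expect_error(generator_config(promoter_peak_fraction = 1.5), "proportion")
  expect_error(generator_config(chrom_length = 100001), "multiple")
})

test_that("the mixed total track closes the 5:1 bulk ratio on flat input", {
  flat <- coverage_track(list(chr1 = rep(1, 200)), 50)
  mixed <- mix_total_sperm(flat, flat, mixture_spec(0.10, 41))
  expect_equal(sum(mixed$counts$chr1) / sum(flat$counts$chr1), 5.0)
  ds <- small_dataset()
  expect_equal(ds$truth$mixture$expected_bulk_ratio, 5.0)
  # on the generated world the bulk ratio is close to, and driven by, the mix
  R_obs <- ds$coverage$total$total_mapped_reads /
    ds$coverage$hrcs$total_mapped_reads
  expect_gt(R_obs, 4); expect_lt(R_obs, 6.5)
})

test_that("planted o/e contrast separates HRCS-target CGIs", {
  ds <- small_dataset()
  tr <- ds$truth$genes
  oe_h <- tr$oe_achieved[tr$category == "H"]
  oe_rest <- tr$oe_achieved[tr$category != "H"]
  expect_gt(min(oe_h), max(0.2, mean(oe_rest)))
  expect_gt(mean(oe_h), 1.0)
  expect_lt(mean(oe_rest), 0.8)
})

test_that("serialized dataset round-trips through the package readers", {
  ds <- generate_dataset(tiny_config(seed = 9))
  d <- withr::local_tempdir()
  files <- write_dataset(ds, d)
  expect_identical(read_genome_fasta(files[["genome"]]), ds$genome)
  expect_equal(read_gene_table(files[["genes"]]), ds$genes)
  pk <- read_bed(files[["peaks_hrcs"]])
  expect_equal(pk[, c("chrom", "start", "end", "name")],
               ds$peaks$hrcs[, c("chrom", "start", "end", "name")])
  tr <- read_bedgraph(files[["coverage_hrcs"]],
                      chrom_sizes = ds$chrom_sizes)
  expect_equal(tr$counts, ds$coverage$hrcs$counts)
  expect_equal(tr$total_mapped_reads, ds$coverage$hrcs$total_mapped_reads)
  ex <- read_expression(files[["expression"]])
  expect_equal(ex$gene_id, ds$expression$gene_id)
  expect_equal(ex$oocyte, ds$expression$oocyte, tolerance = 1e-10)
})
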
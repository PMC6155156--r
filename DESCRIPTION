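Package: spermhist
Title: Histone Retention Analysis for Purified Mature Sperm Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of histone H3 ChIP-seq in
    histone-replacement-completed spermatozoa (HRCS) versus total sperm:
    a simple enrichment screen for peak calling, genomic-compartment
    annotation of peaks (promoter, exon, intron, upstream, downstream,
    intergenic repeat/unique), CpG-island observed/expected ratio
    analysis, peak and target-gene overlap summaries, three-way target
    gene categorization (category_H/PH/TS), TSS-anchored coverage
    matrices and profile curves, region-level bisulfite methylation
    averaging, embryonic expression dynamics, and a two-population
    cell-contamination mixture model.  Ships a self-consistent synthetic
    data generator with planted ground truth so the whole pipeline is
    testable end-to-end without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
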
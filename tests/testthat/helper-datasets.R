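# Shared synthetic datasets, generated once per test run.

.ds_cache <- new.env(parent = emptyenv())

# Small default-world dataset for most planted-truth tests (~seconds).
small_dataset <- function() {
  if (is.null(.ds_cache$small)) {
    cfg <- generator_config(seed = 42, n_chromosomes = 3,
                            chrom_length = 8e5, n_genes = 60,
                            hrcs_peak_count = 30, total_peak_count = 50)
    .ds_cache$small <- generate_dataset(cfg)
  }
  .ds_cache$small
}

# Tiny dataset for determinism / IO round trips (fractions of a second).
tiny_config <- function(seed = 5) {
  generator_config(seed = seed, n_chromosomes = 2, chrom_length = 128000,
                   n_genes = 8, hrcs_peak_count = 4, total_peak_count = 6)
}
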
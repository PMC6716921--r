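# Expensive synthetic genomes built once per test run.

.genome_cache <- new.env()

cached_fig3 <- function() {
  if (is.null(.genome_cache$fig3)) {
    .genome_cache$fig3 <- fig3_genome(seed = 1)
  }
  .genome_cache$fig3
}

cached_benchmark <- function() {
  if (is.null(.genome_cache$benchmark)) {
    .genome_cache$benchmark <- benchmark_genome(seed = 1)
  }
  .genome_cache$benchmark
}
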
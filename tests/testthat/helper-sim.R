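# Shared fixtures, generated in code. Small configs keep the default test
# run fast; the full-size reference condition lives in the acceptance file.

tiny_tiled_map <- function(n = 50, width = 147, spacing = 200, chrom = "chr1") {
  starts <- spacing * (seq_len(n) - 1) + 25
  nucleosome_map(chrom, starts, starts + width)
}

random_fragments <- function(n, chrom = "chr1", max_pos = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- floor(runif(n, 0, max_pos - 200))
  fragments(chrom, start, start + sample(100:200, n, replace = TRUE))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(
        seed = 11, chrom_length_bp = 40000, n_marked = 12, n_artifacts = 4,
        marks = c("H3K4me3", "H3K9ac", "H3K27ac")))
    cache
  }
})

tss_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(
        seed = 5, chrom_length_bp = 800000, n_marked = 120, n_artifacts = 20,
        n_genes = 12))
    cache
  }
})
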
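# Lazily built shared fixtures (generated in code, memoised per test run).

.fixtures <- new.env(parent = emptyenv())

# small planted dataset exercising every kernel
tiny_sim <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- plant_dataset(sim_config(
      n_pos = 30, n_neg = 30, n_chrom = 2, chrom_length = 6e5, seed = 42))
  .fixtures$tiny
}

tiny_cache <- function() {
  if (is.null(.fixtures$tiny_cache))
    .fixtures$tiny_cache <- pirna_feature_cache(tiny_sim()$records,
                                                tiny_sim()$genome)
  .fixtures$tiny_cache
}

tiny_fit <- function() {
  if (is.null(.fixtures$tiny_fit))
    .fixtures$tiny_fit <- pirna_mkl(tiny_sim()$records, tiny_sim()$genome,
                                    C = 1, seed = 1, cache = tiny_cache())
  .fixtures$tiny_fit
}

# single-chromosome genome built from an explicit sequence, with optional
# tracks, for hand-constructed feature cases
toy_genome <- function(seq, tracks = list(), te_annotations = NULL,
                       te_targets = NULL) {
  genome_context(c(chrA = seq), tracks = tracks,
                 te_annotations = te_annotations, te_targets = te_targets)
}

# positions table for a single mapped interval
one_pos <- function(start, end, strand = "+", chrom = "chrA", id = "s1") {
  genomic_intervals(chrom = chrom, start = start, end = end,
                    strand = strand, id = id)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
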
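## Shared fixture builders. All fixtures are generated in code with fixed
## seeds; nothing is read from disk.

random_genome <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reads with explicit integer qualities.
make_read_set <- function(seqs, quals) {
  quality_reads(
    read_id = sprintf("r%03d", seq_along(seqs)),
    seq = seqs,
    qual = vapply(quals, function(q) intToUtf8(q + 33L), "")
  )
}

qstr <- function(q) intToUtf8(q + 33L)

## Distinct random haplotype sequences over a two-letter alphabet (keeps
## pairwise distances informative at short lengths).
random_haps <- function(n, len, seed) {
  set.seed(seed)
  seqs <- unique(vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C"), len, TRUE), collapse = ""), ""
  ))
  setNames(seqs, paste0("H", seq_along(seqs)))
}

## A small deterministic panel used across diagnostics tests.
small_panel_sim <- function(seed = 42L, intra = 0.001, n_clades = 3L,
                            samples = 4L, planted = 10L, len = 2000L) {
  simulate_panel(panel_config(
    n_clades = n_clades, samples_per_clade = samples, genome_length = len,
    planted_fixed_diffs_per_clade = planted, intra_clade_mut_rate = intra,
    seed = seed
  ))
}
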
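test_that("panel construction plants exactly the configured fixed sites", {
  sim <- small_panel_sim(seed = 5L, intra = 0)
  sites <- find_inter_clade_fixed_sites(sim$panel)
  expect_equal(nrow(sites), 30L)
  expect_setequal(sites$column, sim$truth$planted$position)

  ## every clade monomorphic at planted sites, carrying its planted base
  pl <- sim$truth$planted
  for (i in seq_len(nrow(pl))) {
    col <- sites[sites$column == pl$position[i], ]
    expect_equal(col[[paste0("base_", pl$clade[i])]], pl$clade_base[i])
  }
})

test_that("panel simulation is deterministic and noise keeps planted sites", {
  cfg <- panel_config(
    n_clades = 3L, samples_per_clade = 5L, genome_length = 2000L,
    planted_fixed_diffs_per_clade = 10L, intra_clade_mut_rate = 0.001,
    seed = 99L
  )
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$seqs, b$panel$seqs)
  expect_identical(a$references, b$references)

  found <- find_inter_clade_fixed_sites(a$panel)$column
  expect_true(all(a$truth$planted$position %in% found))
  ## oracle agreement on the noisy panel
  expect_equal(found, oracle_fixed_sites(a$panel))
})

test_that("panel config validation rejects bad inputs", {
  expect_error(panel_config(n_clades = 1L), "n_clades")
  expect_error(panel_config(genome_length = 100L), "genome_length")
  expect_error(panel_config(intra_clade_mut_rate = 0.2), "intra_clade")
  expect_error(
    panel_config(
      genome_length = 1000L, n_clades = 4L,
      planted_fixed_diffs_per_clade = 300L
    ),
    "exceed"
  )
})

test_that("noise-free reads are exact circular substrings of the genome", {
  g <- random_genome(2000, seed = 2L)
  rs <- simulate_reads(g, read_sim_params(
    n_fragments = 300L, d5 = 0, d3 = 0, seq_error = 0, dup_rate = 0,
    seed = 8L
  ))
  pad <- paste0(g, g)
  for (i in seq_len(nrow(rs$reads))) {
    t <- rs$truth[i, ]
    frag <- substr(pad, t$start + 1L, t$start + t$length)
    expected <- if (t$strand == "-") revcomp(frag) else frag
    expect_identical(rs$reads$seq[i], expected)
  }
  expect_true(all(rs$truth$wrap == (rs$truth$start + rs$truth$length > 2000)))
})

test_that("read simulation is reproducible byte-for-byte", {
  g <- random_genome(1500, seed = 3L)
  p <- read_sim_params(n_fragments = 200L, dup_rate = 0.1, seed = 21L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, p)$reads, f1)
  write_fastq(simulate_reads(g, p)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("terminal damage frequencies follow d * lambda^i on truth counts", {
  g <- random_genome(4000, seed = 4L)
  p <- read_sim_params(
    n_fragments = 20000L, d5 = 0.05, d3 = 0.03, lambda = 0.5,
    seq_error = 0, dup_rate = 0, seed = 13L
  )
  rs <- simulate_reads(g, p)
  dp <- damage_profile(true_alignments(rs), g, n_positions = 6L)
  for (i in 1:4) {
    expected <- p$d5 * p$lambda^(i - 1)
    n <- dp$opp5[i, "C>T"]
    sd3 <- 3 * sqrt(expected * (1 - expected) / n)
    expect_lt(abs(dp$freq5[i, "C>T"] - expected), sd3 + 1e-12)
    expected3 <- p$d3 * p$lambda^(i - 1)
    sd3b <- 3 * sqrt(expected3 * (1 - expected3) / dp$opp3[i, "G>A"])
    expect_lt(abs(dp$freq3[i, "G>A"] - expected3), sd3b + 1e-12)
  }
})

test_that("duplicate fraction matches dup_rate within 3 binomial SD", {
  g <- random_genome(3000, seed = 6L)
  p <- read_sim_params(n_fragments = 20000L, dup_rate = 0.25, seed = 31L)
  rs <- simulate_reads(g, p)
  n <- nrow(rs$reads)
  frac <- sum(rs$truth$is_duplicate) / n
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  ## duplicates are exact copies of their group representative
  grp <- split(seq_len(n), rs$truth$dup_group)
  grp <- grp[lengths(grp) > 1L]
  for (g_idx in grp[seq_len(min(20L, length(grp)))]) {
    expect_equal(length(unique(rs$reads$seq[g_idx])), 1L)
  }
})

test_that("contamination mixing hits the requested fraction and edge cases", {
  g1 <- random_genome(2000, seed = 7L)
  g2 <- random_genome(2000, seed = 8L)
  e <- simulate_reads(g1, read_sim_params(n_fragments = 12000L, seed = 1L),
    label = "endo"
  )
  c <- simulate_reads(g2, read_sim_params(n_fragments = 4000L, seed = 2L),
    label = "cont"
  )

  pool0 <- mix_contamination(e, c, 0)
  expect_identical(pool0$reads$read_id, e$reads$read_id)

  pool1 <- mix_contamination(e, c, 1, n = 3000L)
  expect_true(all(pool1$truth$source == "cont"))

  pool <- mix_contamination(e, c, 0.1, n = 10000L, seed = 5L)
  k <- sum(pool$truth$source == "cont")
  expect_lt(abs(k - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_false(anyDuplicated(pool$reads$read_id) > 0L)

  ## id collision is an error
  e2 <- simulate_reads(g2, read_sim_params(n_fragments = 100L, seed = 3L),
    label = "endo"
  )
  expect_error(mix_contamination(e, e2, 0.5), "collision")
})

test_that("simulator rejects invalid inputs", {
  expect_error(read_sim_params(n_fragments = 0L), "positive")
  expect_error(read_sim_params(d5 = 0.5), "d5")
  expect_error(read_sim_params(lambda = 1), "lambda")
  expect_error(
    simulate_reads("ACGTNACGT", read_sim_params(n_fragments = 10L)),
    "A/C/G/T"
  )
  expect_error(
    simulate_reads(substr(random_genome(100), 1, 20),
      read_sim_params(n_fragments = 10L)
    ),
    "shorter"
  )
})

test_that("FASTQ and truth round-trip through files", {
  g <- random_genome(1500, seed = 9L)
  rs <- simulate_reads(g, read_sim_params(n_fragments = 50L, seed = 4L))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs$reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$seq, rs$reads$seq)
  expect_identical(back$qual, rs$reads$qual)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth(rs, tsv)
  tt <- read.delim(tsv)
  expect_identical(nrow(tt), nrow(rs$truth))
})
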
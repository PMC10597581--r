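test_that("exact substrings map to their true position, edit 0, unique", {
  g <- random_genome(3000, seed = 11L)
  read <- substr(g, 1001L, 1050L)
  m <- map_read(read, qstr(rep(37L, 50L)), ref_index(g), read_id = "x")
  expect_equal(m$start, 1000L)
  expect_equal(m$edit, 0L)
  expect_true(m$unique_best)
  expect_equal(m$strand, "+")

  ## reverse-complemented read maps to the same coordinates on -
  m2 <- map_read(revcomp(read), qstr(rep(37L, 50L)), ref_index(g))
  expect_equal(m2$start, 1000L)
  expect_equal(m2$strand, "-")
  expect_equal(m2$seq, read) # stored reference-oriented
})

test_that("origin-spanning reads map with wrap", {
  g <- random_genome(2000, seed = 12L)
  read <- paste0(substr(g, 1981L, 2000L), substr(g, 1L, 30L))
  m <- map_read(read, qstr(rep(37L, 50L)), ref_index(g))
  expect_equal(m$start, 1980L)
  expect_equal(m$edit, 0L)
})

test_that("simulated error-free reads recover their true coordinates", {
  g <- random_genome(4000, seed = 13L)
  rs <- simulate_reads(g, read_sim_params(
    n_fragments = 1000L, d5 = 0, d3 = 0, seq_error = 0, dup_rate = 0,
    seed = 14L
  ))
  mp <- map_reads(rs$reads, g)
  hit <- merge(as.data.frame(mp), rs$truth, by = "read_id")
  correct <- hit$start.x == hit$start.y & hit$strand.x == hit$strand.y
  expect_gte(mean(correct) * nrow(hit) / 1000, 0.99)
})

test_that("ambiguous-only reads are unmapped, not an error", {
  g <- random_genome(2000, seed = 15L)
  m <- map_read(strrep("N", 40L), qstr(rep(37L, 40L)), ref_index(g))
  expect_null(m)
})

test_that("best-reference selection picks the source clade", {
  sim <- small_panel_sim(seed = 21L, intra = 0, planted = 25L)
  rs <- simulate_reads(
    sim$references[["cladeA"]],
    read_sim_params(n_fragments = 400L, seed = 22L)
  )
  sel <- select_best_reference(
    rs$reads, sim$references[c("cladeA", "cladeB")]
  )
  expect_equal(sel$best_ref, "cladeA")
  expect_false(sel$tie)
  expect_equal(nrow(sel$table), 2L)

  ## identical references tie, resolved lexicographically and flagged
  refs <- c(zz = sim$references[["cladeA"]], aa = sim$references[["cladeA"]])
  sel2 <- select_best_reference(rs$reads, refs)
  expect_equal(sel2$best_ref, "aa")
  expect_true(sel2$tie)

  ## permutation invariance of the winner
  sel3 <- select_best_reference(
    rs$reads, sim$references[c("cladeB", "cladeA")]
  )
  expect_equal(sel3$best_ref, "cladeA")
})

test_that("select_best_reference errors when nothing maps", {
  g1 <- random_genome(2000, seed = 23L)
  reads <- make_read_set(
    rep(strrep("N", 40L), 3L),
    replicate(3, rep(37L, 40L), simplify = FALSE)
  )
  expect_error(
    select_best_reference(reads, c(a = g1, b = random_genome(2000, 24L))),
    "no reference compatible"
  )
})

test_that("deduplication keys on (ref, start, end, strand)", {
  mk <- function(id, start, len, strand, q = 37L) {
    mapped_reads(
      read_id = id, ref_id = "r", start = start, strand = strand,
      cigar = paste0(len, "M"), seq = strrep("A", len),
      qual = qstr(rep(q, len)), edit = 0L, score = len, unique_best = TRUE
    )
  }
  two <- rbind(mk("a", 10L, 30L, "+"), mk("b", 10L, 30L, "+", q = 39L))
  class(two) <- c("mapped_reads", "data.frame")
  dd <- deduplicate(two)
  expect_equal(nrow(dd$reads), 1L)
  expect_equal(dd$reads$read_id, "b") # highest summed quality wins
  expect_equal(dd$stats$duplication_level, 0.5)

  ## same start, different end -> both retained
  three <- rbind(mk("a", 10L, 30L, "+"), mk("b", 10L, 31L, "+"))
  class(three) <- c("mapped_reads", "data.frame")
  expect_equal(nrow(deduplicate(three)$reads), 2L)

  ## same coordinates, opposite strand -> both retained
  four <- rbind(mk("a", 10L, 30L, "+"), mk("b", 10L, 30L, "-"))
  class(four) <- c("mapped_reads", "data.frame")
  expect_equal(nrow(deduplicate(four)$reads), 2L)
})

test_that("simulated duplication level is recovered after mapping", {
  g <- random_genome(3000, seed = 25L)
  rs <- simulate_reads(g, read_sim_params(
    n_fragments = 4000L, dup_rate = 0.25, d5 = 0, d3 = 0, seq_error = 0,
    seed = 26L
  ))
  mp <- map_reads(rs$reads, g)
  dd <- deduplicate(mp)
  expect_lt(
    abs(dd$stats$duplication_level - 0.25),
    3 * sqrt(0.25 * 0.75 / 4000) + 0.02 # + coincidental-coordinate slack
  )
})

test_that("pileup counts match the documented examples", {
  mk <- function(id, start, seq) {
    mapped_reads(
      read_id = id, ref_id = "r", start = start, strand = "+",
      cigar = paste0(nchar(seq), "M"), seq = seq,
      qual = qstr(rep(37L, nchar(seq))), edit = 0L, score = nchar(seq),
      unique_best = TRUE
    )
  }
  two <- rbind(mk("a", 0L, strrep("A", 10L)), mk("b", 50L, strrep("C", 10L)))
  class(two) <- c("mapped_reads", "data.frame")
  pl <- make_pileup(two, 100L)
  expect_equal(sum(pl$depth == 1L), 20L)
  expect_equal(mean(pl$depth), 0.2)

  ## single mismatch contributes the observed base
  g <- random_genome(100, seed = 27L)
  r <- substr(g, 11L, 40L)
  substr(r, 5L, 5L) <- "T"
  one <- mk("m", 10L, r)
  pl2 <- make_pileup(one, 100L)
  expect_equal(unname(pl2$counts["T", 15L]), 1L)
})

test_that("pileup equals the brute-force recount, including indels", {
  g <- random_genome(500, seed = 28L)
  rs <- simulate_reads(g, read_sim_params(n_fragments = 150L, seed = 29L))
  mp <- map_reads(rs$reads, g)
  pl <- make_pileup(mp, 500L)
  expect_identical(pl$counts, oracle_pileup(mp, 500L))

  ## conservation: total base count equals total aligned read bases
  expect_equal(sum(pl$counts[1:4, ]), sum(nchar(mp$seq)))

  ## gapped alignments via SAM import
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:r\tLN:100",
    paste0("g1\t0\tr\t11\t60\t10M2D10M\t*\t0\t0\t", strrep("A", 20L),
      "\t", qstr(rep(37L, 20L)), "\tNM:i:2"),
    paste0("g2\t16\tr\t31\t60\t5M1I4M\t*\t0\t0\t", strrep("C", 10L),
      "\t", qstr(rep(37L, 10L)), "\tNM:i:1")
  ), sam)
  imp <- read_sam(sam)
  expect_equal(imp$ref_length, 100L)
  pl3 <- make_pileup(imp$reads, 100L)
  expect_identical(pl3$counts, oracle_pileup(imp$reads, 100L))
  expect_equal(unname(pl3$counts["-", 21L]), 1L) # deletion track
})

test_that("SAM round trip preserves alignments", {
  g <- random_genome(1000, seed = 30L)
  rs <- simulate_reads(g, read_sim_params(n_fragments = 60L, seed = 31L))
  mp <- map_reads(rs$reads, g, ref_id = "mito")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(mp, sam, 1000L)
  back <- read_sam(sam)
  expect_equal(back$ref_length, 1000L)
  expect_identical(back$reads$read_id, mp$read_id)
  expect_identical(back$reads$start, mp$start)
  expect_identical(back$reads$strand, mp$strand)
  expect_identical(back$reads$seq, mp$seq)
  expect_identical(back$reads$edit, mp$edit)
})

test_that("dedup after mapping never increases depth anywhere", {
  g <- random_genome(1000, seed = 32L)
  rs <- simulate_reads(g, read_sim_params(
    n_fragments = 500L, dup_rate = 0.3, seed = 33L
  ))
  mp <- map_reads(rs$reads, g)
  before <- make_pileup(mp, 1000L)$depth
  after <- make_pileup(deduplicate(mp)$reads, 1000L)$depth
  expect_true(all(after <= before))
})
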
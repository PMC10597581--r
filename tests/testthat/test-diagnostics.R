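## A tiny hand-buildable panel: two clades, three samples each.
tiny_panel <- function(seqs_a, seqs_b) {
  seqs <- c(seqs_a, seqs_b)
  names(seqs) <- c(
    paste0("a", seq_along(seqs_a)),
    paste0("b", seq_along(seqs_b))
  )
  clade_panel(seqs, data.frame(
    sample_id = names(seqs),
    clade = rep(c("A", "B"), c(length(seqs_a), length(seqs_b)))
  ))
}

test_that("inter-clade fixed site discovery follows the definition", {
  ## monomorphic everywhere, one differing column (index 3, 0-based)
  p <- tiny_panel(
    rep("ACGTACGT", 3L),
    rep("ACGAACGT", 3L)
  )
  s <- find_inter_clade_fixed_sites(p)
  expect_equal(s$column, 3L)
  expect_equal(s$base_A, "T")
  expect_equal(s$base_B, "A")

  ## a column polymorphic within one clade is excluded
  p2 <- tiny_panel(
    c("ACGTACGT", "ACGCACGT", "ACGTACGT"),
    rep("ACGAACGT", 3L)
  )
  expect_equal(nrow(find_inter_clade_fixed_sites(p2)), 0L)

  ## missing data: all-missing clade contributes no constraint
  p3 <- tiny_panel(
    c("ACGNACGT", "ACGNACGT", "ACGNACGT"),
    rep("ACGAACGT", 3L)
  )
  ## column 3 has 3/6 = 50% missing > 10% -> excluded by missing filter
  expect_equal(nrow(find_inter_clade_fixed_sites(p3)), 0L)
  ## with a permissive missing threshold it still yields no site (only one
  ## clade has data there)
  expect_equal(nrow(find_inter_clade_fixed_sites(p3, 0.6)), 0L)
})

test_that("site discovery equals the exhaustive per-column oracle", {
  for (seed in c(61L, 62L, 63L)) {
    sim <- small_panel_sim(seed = seed, intra = 0.002)
    mine <- find_inter_clade_fixed_sites(sim$panel)$column
    expect_equal(mine, oracle_fixed_sites(sim$panel))
  }
})

test_that("query-divergent site discovery matches construction", {
  p <- tiny_panel(rep(strrep("ACGT", 25L), 3L), rep(strrep("TGCA", 25L), 3L))
  q <- strrep("ACGT", 25L)
  expect_equal(
    nrow(find_clade_fixed_query_divergent_sites(p, "A", q)), 0L
  )
  ## plant 5 private substitutions
  qq <- q
  for (pos in c(3L, 10L, 41L, 77L, 98L)) {
    old <- substr(qq, pos, pos)
    substr(qq, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  s <- find_clade_fixed_query_divergent_sites(p, "A", qq)
  expect_equal(s$column, c(3L, 10L, 41L, 77L, 98L) - 1L)
  expect_equal(s$focal_base, vapply(
    c(3L, 10L, 41L, 77L, 98L),
    function(i) substr(qq, i, i), ""
  ))
  ## N in the query is not divergence
  qn <- q
  substr(qn, 7L, 7L) <- "N"
  expect_equal(
    nrow(find_clade_fixed_query_divergent_sites(p, "A", qn)), 0L
  )
  expect_error(
    find_clade_fixed_query_divergent_sites(p, "Z", q), "absent"
  )
})

test_that("query-divergent sites agree with a brute-force scan", {
  sim <- small_panel_sim(seed = 64L, intra = 0.002)
  ref <- sim$references[["cladeB"]]
  set.seed(65)
  q <- strsplit(ref, "")[[1]]
  muts <- sample(nchar(ref), 12L)
  for (p in muts) q[p] <- setdiff(c("A", "C", "G", "T"), q[p])[1]
  q <- paste(q, collapse = "")
  s <- find_clade_fixed_query_divergent_sites(sim$panel, "cladeB", q)

  ## oracle: per column, clade B monomorphic base vs query base
  m <- do.call(rbind, strsplit(
    sim$panel$seqs[sim$panel$labels$clade == "cladeB"], ""
  ))
  qs <- strsplit(q, "")[[1]]
  exp_cols <- integer(0)
  for (col in seq_len(ncol(m))) {
    b <- unique(m[, col][!m[, col] %in% c("N", "-")])
    if (length(b) == 1L && qs[col] %in% c("A", "C", "G", "T") &&
      qs[col] != b) {
      exp_cols <- c(exp_cols, col - 1L)
    }
  }
  expect_equal(s$column, exp_cols)
})

test_that("site agreement: perfect support gives median 1, IQR 0", {
  sim <- small_panel_sim(seed = 66L, intra = 0)
  ref <- sim$references[["cladeA"]]
  rs <- simulate_reads(ref, read_sim_params(
    n_fragments = 600L, d5 = 0, d3 = 0, seq_error = 0, seed = 67L
  ))
  pl <- make_pileup(map_reads(rs$reads, ref), nchar(ref))
  sites <- find_inter_clade_fixed_sites(sim$panel, focal_clade = "cladeA")
  ag <- site_agreement(pl, sites)
  expect_equal(ag$median, 1.0)
  expect_equal(ag$iqr, 0.0)
  expect_equal(ag$n_sites + ag$n_zero_coverage, nrow(sites))
})

test_that("median and IQR agree with a direct sort-based computation", {
  sim <- small_panel_sim(seed = 68L, intra = 0)
  ref <- sim$references[["cladeA"]]
  rs <- simulate_reads(ref, read_sim_params(
    n_fragments = 500L, seq_error = 0.02, seed = 69L
  ))
  pl <- make_pileup(map_reads(rs$reads, ref), nchar(ref))
  sites <- find_inter_clade_fixed_sites(sim$panel, focal_clade = "cladeA")
  ag <- site_agreement(pl, sites)
  a <- ag$per_site$agreement[!is.na(ag$per_site$agreement)]
  srt <- sort(a)
  n <- length(srt)
  med <- if (n %% 2L) srt[(n + 1L) / 2L] else (srt[n / 2L] + srt[n / 2L + 1L]) / 2
  expect_equal(ag$median, med)
  q1 <- stats::quantile(a, 0.25, type = 7, names = FALSE)
  q3 <- stats::quantile(a, 0.75, type = 7, names = FALSE)
  expect_equal(ag$iqr, q3 - q1)
})

test_that("site agreement errors when every site is uncovered", {
  sim <- small_panel_sim(seed = 70L, intra = 0)
  empty <- mapped_reads(
    character(0), character(0), integer(0), character(0), character(0),
    character(0), character(0), integer(0), integer(0), logical(0)
  )
  pl <- make_pileup(empty, 2000L)
  sites <- find_inter_clade_fixed_sites(sim$panel, focal_clade = "cladeA")
  expect_error(site_agreement(pl, sites), "uncovered")
})

test_that("clade assignment: consensus and leave-one-out recovery", {
  sim <- small_panel_sim(seed = 71L, intra = 0.002, samples = 3L)
  sites <- find_inter_clade_fixed_sites(sim$panel)

  ## the clade consensus assigns to its own clade with full votes
  asn <- assign_clade(sim$references[["cladeC"]], sim$panel, sites)
  expect_equal(asn$assigned, "cladeC")
  expect_equal(
    unname(asn$votes["cladeC"]),
    asn$n_usable_sites
  )

  ## leave-one-out over every panel member
  for (i in seq_along(sim$panel$seqs)) {
    keep <- setdiff(seq_along(sim$panel$seqs), i)
    sub <- clade_panel(
      sim$panel$seqs[keep], sim$panel$labels[keep, , drop = FALSE]
    )
    got <- assign_clade(sim$panel$seqs[[i]], sub)
    expect_equal(got$assigned, sim$panel$labels$clade[i])
  }
})

test_that("assignment errors without usable sites", {
  sim <- small_panel_sim(seed = 72L, intra = 0)
  allN <- strrep("N", nchar(sim$panel$seqs[1]))
  expect_error(assign_clade(allN, sim$panel), "unassignable")
})

test_that("region extraction and missing-data filtering", {
  aln <- c(
    s1 = strrep("ACGT", 100L), # 400 columns
    s2 = strrep("ACGT", 100L),
    s3 = paste0(strrep("N", 18L), strrep("ACGT", 95L), "AC")
  )
  sub <- extract_region(aln, c(0L, 176L))
  expect_true(all(nchar(sub) == 176L))
  expect_error(extract_region(aln, c(10L, 10L)), "empty")
  expect_error(extract_region(aln, c(0L, 500L)), "outside")

  ## 18/176 = 10.2% N -> removed; 17/176 = 9.7% -> kept
  x <- c(
    keep = paste0(strrep("N", 17L), strrep("A", 159L)),
    drop = paste0(strrep("N", 18L), strrep("A", 158L))
  )
  f <- filter_missing(x, 0.10)
  expect_equal(names(f), "keep")
  expect_equal(attr(f, "removed")$sample_id, "drop")

  ## extract-then-filter differs from filter-then-extract by construction
  aln2 <- c(
    u = paste0(strrep("N", 30L), strrep("A", 70L)), # 30% N overall
    v = strrep("A", 100L),
    w = strrep("C", 100L)
  )
  ef <- filter_missing(extract_region(aln2, c(40L, 100L)), 0.10)
  expect_true("u" %in% names(ef)) # clean in the slice
  fe <- extract_region(filter_missing(aln2, 0.10), c(40L, 100L))
  expect_false("u" %in% names(fe)) # dropped before slicing
})

test_that("panel column to reference coordinate mapping skips gaps", {
  p <- clade_panel(
    c(r = "AC-GT", s = "ACAGT", t = "ACCGT", u = "ATAGA"),
    data.frame(
      sample_id = c("r", "s", "t", "u"),
      clade = c("X", "X", "Y", "Y")
    )
  )
  coords <- panel_to_ref_coords(p, "r")
  expect_equal(coords, c(0L, 1L, NA_integer_, 2L, 3L))
})
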
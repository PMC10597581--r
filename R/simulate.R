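#' Configuration for a synthetic clade panel
#'
#' Describes a multi-clade mitogenome panel: one root genome, a set of
#' clade-diagnostic ("planted") substitutions fixed within each clade, and
#' per-sample private substitutions. Stands in for a curated panel of
#' georeferenced mitogenomes with clade labels.
#'
#' @param n_clades number of clades (>= 2).
#' @param samples_per_clade samples per clade (>= 1).
#' @param genome_length genome length in bp (>= 1000).
#' @param planted_fixed_diffs_per_clade number of clade-unique fixed
#'   substitutions planted per clade.
#' @param intra_clade_mut_rate per-site probability of a private
#'   substitution in each sample (0 <= rate < 0.05).
#' @param seed integer seed.
#' @return a `panel_config` list.
#' @export
panel_config <- function(n_clades = 3L, samples_per_clade = 5L,
                         genome_length = 16000L,
                         planted_fixed_diffs_per_clade = 25L,
                         intra_clade_mut_rate = 0.001, seed = 1L) {
  cfg <- list(
    n_clades = as.integer(n_clades),
    samples_per_clade = as.integer(samples_per_clade),
    genome_length = as.integer(genome_length),
    planted_fixed_diffs_per_clade = as.integer(planted_fixed_diffs_per_clade),
    intra_clade_mut_rate = as.numeric(intra_clade_mut_rate),
    seed = as.integer(seed)
  )
  if (cfg$n_clades < 2L) stop("n_clades must be >= 2")
  if (cfg$samples_per_clade < 1L) stop("samples_per_clade must be >= 1")
  if (cfg$genome_length < 1000L) stop("genome_length must be >= 1000")
  if (cfg$intra_clade_mut_rate < 0 || cfg$intra_clade_mut_rate >= 0.05) {
    stop("intra_clade_mut_rate must be in [0, 0.05)")
  }
  if (cfg$n_clades * cfg$planted_fixed_diffs_per_clade > cfg$genome_length) {
    stop("planted positions exceed genome_length")
  }
  class(cfg) <- "panel_config"
  cfg
}

#' Simulate a clade panel and per-clade reference mitogenomes
#'
#' Draws one random root genome, plants `planted_fixed_diffs_per_clade`
#' substitutions per clade at clade-unique positions (shared by every sample
#' of the clade, absent from all others), then adds per-sample private
#' substitutions at rate `intra_clade_mut_rate`, never at planted positions.
#' No indels are simulated, so the panel is trivially aligned and panel
#' columns coincide with reference coordinates.
#'
#' @param config a [panel_config()].
#' @return a list with components:
#'   \item{panel}{a [clade_panel()] of all samples.}
#'   \item{references}{named character vector of per-clade consensus
#'     genomes (majority base per column).}
#'   \item{truth}{list with the root genome and a data frame of planted
#'     sites (`position` 0-based, `clade`, `root_base`, `clade_base`).}
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  L <- config$genome_length
  root <- sample(DNA_BASES, L, replace = TRUE)

  n_planted <- config$n_clades * config$planted_fixed_diffs_per_clade
  planted_pos <- sort(sample.int(L, n_planted)) # 1-based internally
  clade_of_pos <- rep(seq_len(config$n_clades),
    each = config$planted_fixed_diffs_per_clade
  )
  clade_of_pos <- clade_of_pos[sample.int(n_planted)]

  clade_names <- paste0("clade", LETTERS[seq_len(config$n_clades)])
  ## clade base sequences: root + planted diffs of that clade
  clade_seqs <- list()
  planted <- data.frame(
    position = planted_pos - 1L,
    clade = clade_names[clade_of_pos],
    root_base = root[planted_pos],
    clade_base = NA_character_
  )
  for (ci in seq_len(config$n_clades)) {
    s <- root
    idx <- planted_pos[clade_of_pos == ci]
    for (p in idx) {
      s[p] <- sample(setdiff(DNA_BASES, root[p]), 1L)
    }
    planted$clade_base[match(idx - 1L, planted$position)] <- s[idx]
    clade_seqs[[clade_names[ci]]] <- s
  }

  ## per-sample private substitutions, never at any planted position
  sample_seqs <- character(0)
  sample_id <- character(0)
  clade_lab <- character(0)
  free_pos <- setdiff(seq_len(L), planted_pos)
  for (ci in seq_len(config$n_clades)) {
    base_seq <- clade_seqs[[clade_names[ci]]]
    for (si in seq_len(config$samples_per_clade)) {
      s <- base_seq
      if (config$intra_clade_mut_rate > 0) {
        hit <- free_pos[runif(length(free_pos)) < config$intra_clade_mut_rate]
        for (p in hit) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
      }
      id <- sprintf("%s_s%02d", clade_names[ci], si)
      sample_id <- c(sample_id, id)
      clade_lab <- c(clade_lab, clade_names[ci])
      sample_seqs <- c(sample_seqs, paste(s, collapse = ""))
    }
  }
  names(sample_seqs) <- sample_id

  ## synthetic provenance metadata mirroring a museum-panel sidecar
  labels <- data.frame(
    sample_id = sample_id,
    clade = clade_lab,
    species = paste0("P. synthetica-", tolower(substr(clade_lab, 6L, 6L))),
    latitude = round(10 + 2 * match(clade_lab, clade_names) +
      seq_along(sample_id) %% 5 / 10, 3),
    longitude = round(35 + 1.5 * match(clade_lab, clade_names) +
      seq_along(sample_id) %% 7 / 10, 3)
  )
  panel <- clade_panel(sample_seqs, labels)

  ## per-clade reference = clade consensus (majority; ties to the clade base)
  refs <- vapply(clade_names, function(cn) {
    m <- seq_matrix(sample_seqs[clade_lab == cn])
    cons <- clade_seqs[[cn]]
    if (nrow(m) > 1L) {
      for (j in seq_len(ncol(m))) {
        tab <- table(m[, j])
        top <- names(tab)[tab == max(tab)]
        if (length(top) == 1L) cons[j] <- top
        ## tie: keep the clade base (already in cons)
      }
    } else {
      cons <- m[1L, ]
    }
    paste(cons, collapse = "")
  }, character(1))

  list(
    panel = panel,
    references = refs,
    truth = list(root = paste(root, collapse = ""), planted = planted)
  )
}

#' Parameters for the ancient-read simulator
#'
#' Fragment lengths are log-normal (moment-matched to `frag_len_mean` /
#' `frag_len_sd` on the natural scale) truncated to `[30, 150]` bp by
#' rejection. Post-mortem deamination is modelled as C->T at the 5' end and
#' G->A at the 3' end with geometrically decaying probability
#' `d5 * lambda^i` (offset `i` counted into the read from the respective
#' end). Sequencing error is uniform per base; a fraction `dup_rate` of
#' emitted reads are exact copies of an already-emitted read (PCR
#' duplicates). Qualities are two-level: `qual_high` everywhere except
#' damaged or erroneous bases, which get `qual_low`.
#'
#' @param n_fragments number of reads to emit.
#' @param frag_len_mean,frag_len_sd fragment length moments in bp.
#' @param d5,d3 damage probabilities at offset 0 (each in `[0, 0.2]`).
#' @param lambda geometric decay per base (0 < lambda < 1).
#' @param seq_error per-base sequencing error probability.
#' @param dup_rate fraction of emitted reads that are duplicates.
#' @param qual_high,qual_low Phred values for clean/uncertain bases. The
#'   default `qual_low = 25` sits below `qual_high` but above the usual
#'   end-trimming thresholds (Phred 20): a sequencer reads a deaminated
#'   base confidently, so damaged termini must survive quality trimming as
#'   they do in real ancient-DNA data.
#' @param seed integer seed.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(n_fragments = 10000L, frag_len_mean = 60,
                            frag_len_sd = 15, d5 = 0.033, d3 = 0.016,
                            lambda = 0.5, seq_error = 0.001, dup_rate = 0,
                            qual_high = 37L, qual_low = 25L, seed = 1L) {
  p <- list(
    n_fragments = as.integer(n_fragments), frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd, d5 = d5, d3 = d3, lambda = lambda,
    seq_error = seq_error, dup_rate = dup_rate,
    qual_high = as.integer(qual_high), qual_low = as.integer(qual_low),
    seed = as.integer(seed)
  )
  if (p$n_fragments <= 0L) stop("n_fragments must be positive")
  if (p$d5 < 0 || p$d5 > 0.2 || p$d3 < 0 || p$d3 > 0.2) {
    stop("d5 and d3 must be in [0, 0.2]")
  }
  if (p$lambda <= 0 || p$lambda >= 1) stop("lambda must be in (0, 1)")
  if (p$dup_rate < 0 || p$dup_rate >= 1) stop("dup_rate must be in [0, 1)")
  class(p) <- "read_sim_params"
  p
}

MIN_FRAG <- 30L
MAX_FRAG <- 150L

#' Simulate ancient single-end reads from a circular genome
#'
#' Fragment starts are uniform on the circle, strands uniform; fragments may
#' span the origin (recorded with a wrap flag). Damage is applied in read
#' orientation before sequencing error. Complete ground truth is returned:
#' source label, true coordinates, strand, wrap, duplicate groups, and the
#' read-coordinate positions of every damage- and error-induced
#' substitution.
#'
#' @param genome a single A/C/G/T string (circular).
#' @param params a [read_sim_params()].
#' @param label provenance label for these reads (also the read-id prefix).
#' @return a `sim_reads` list with components `reads` ([quality_reads()]),
#'   `truth` (data frame), and `params`.
#' @export
simulate_reads <- function(genome, params, label = "endo") {
  stopifnot(inherits(params, "read_sim_params"))
  genome <- toupper(genome)
  if (grepl("[^ACGT]", genome)) stop("genome must contain only A/C/G/T")
  L <- nchar(genome)
  if (L < MIN_FRAG) stop("genome shorter than minimum fragment length")
  set.seed(params$seed)
  n <- params$n_fragments

  ## duplicate structure: read t (t>1) is a copy of an earlier read with
  ## probability dup_rate
  is_dup <- c(FALSE, runif(n - 1L) < params$dup_rate)
  n_orig <- sum(!is_dup)

  ## fragment lengths: moment-matched log-normal, truncated by rejection
  m <- params$frag_len_mean
  s <- params$frag_len_sd
  sdlog <- sqrt(log(1 + s^2 / m^2))
  meanlog <- log(m) - sdlog^2 / 2
  lens <- integer(0)
  while (length(lens) < n_orig) {
    draw <- as.integer(round(rlnorm(n_orig, meanlog, sdlog)))
    lens <- c(lens, draw[draw >= MIN_FRAG & draw <= min(MAX_FRAG, L)])
  }
  lens <- lens[seq_len(n_orig)]

  starts <- as.integer(floor(runif(n_orig) * L)) # 0-based
  strands <- ifelse(runif(n_orig) < 0.5, "+", "-")
  frag <- circular_substr(genome, starts, lens)
  seqs <- frag$seq
  neg <- strands == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

  ## flatten to per-base vectors for vectorised damage + error
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  ridx <- rep.int(seq_len(n_orig), lens)
  off5 <- sequence(lens) - 1L
  off3 <- rep.int(lens, lens) - 1L - off5

  p_dam <- numeric(length(chars))
  p_dam[chars == "C"] <- params$d5 * params$lambda^off5[chars == "C"]
  p_dam[chars == "G"] <- params$d3 * params$lambda^off3[chars == "G"]
  dam <- runif(length(chars)) < p_dam
  chars[dam & chars == "C"] <- "T"
  chars[dam & chars == "G"] <- "A"

  err <- runif(length(chars)) < params$seq_error
  if (any(err)) {
    cur <- chars[err]
    alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    chars[err] <- alt
  }

  quals <- rep.int(params$qual_high, length(chars))
  quals[dam | err] <- params$qual_low

  ## reassemble per-read strings via one big string + substring
  ends <- cumsum(lens)
  begins <- ends - lens + 1L
  all_seq <- paste(chars, collapse = "")
  all_qual <- intToUtf8(quals + 33L)
  oseq <- substring(all_seq, begins, ends)
  oqual <- substring(all_qual, begins, ends)
  dam_pos <- split(off5[dam], factor(ridx[dam], levels = seq_len(n_orig)))
  err_pos <- split(off5[err], factor(ridx[err], levels = seq_len(n_orig)))

  ## interleave originals and duplicates in emission order
  orig_slot <- cumsum(!is_dup) # which original each position would be
  content <- integer(n) # index into originals
  for (i in seq_len(n)) {
    if (!is_dup[i]) {
      content[i] <- orig_slot[i]
    } else {
      content[i] <- content[sample.int(i - 1L, 1L)]
    }
  }
  dup_group <- content

  ids <- sprintf("%s_%06d", label, seq_len(n))
  reads <- quality_reads(ids, oseq[content], oqual[content],
    source = rep(label, n)
  )
  truth <- data.frame(
    read_id = ids,
    source = label,
    start = starts[content],
    end = (starts[content] + lens[content]) %% L,
    length = lens[content],
    strand = strands[content],
    wrap = frag$wrap[content],
    dup_group = sprintf("%s_g%06d", label, dup_group),
    is_duplicate = is_dup,
    stringsAsFactors = FALSE
  )
  truth$damage_pos <- unname(dam_pos[content])
  truth$error_pos <- unname(err_pos[content])
  structure(
    list(reads = reads, truth = truth, params = params, genome_length = L),
    class = "sim_reads"
  )
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "sim_reads: %d reads (%d duplicates), genome length %d\n",
    nrow(x$reads), sum(x$truth$is_duplicate), x$genome_length
  ))
  invisible(x)
}

#' Pool endogenous and contaminant reads
#'
#' Draws a binomial number `k ~ Bin(n, fraction)` of contaminant reads
#' (without replacement) and `n - k` endogenous reads, preserving input
#' order within each source. Truth labels follow each read into the pool.
#'
#' @param endogenous,contaminant `sim_reads` objects (with distinct read-id
#'   prefixes; an id collision is an error).
#' @param fraction expected contaminant share in `[0, 1]`.
#' @param n pool size; defaults to the number of endogenous reads.
#' @param seed integer seed.
#' @return a `sim_reads` object for the pool.
#' @export
mix_contamination <- function(endogenous, contaminant, fraction,
                              n = nrow(endogenous$reads), seed = 1L) {
  stopifnot(
    inherits(endogenous, "sim_reads"), inherits(contaminant, "sim_reads"),
    fraction >= 0, fraction <= 1
  )
  if (any(endogenous$reads$read_id %in% contaminant$reads$read_id)) {
    stop("read id collision between endogenous and contaminant sets")
  }
  set.seed(seed)
  k <- sum(runif(n) < fraction)
  if (k > nrow(contaminant$reads)) stop("not enough contaminant reads")
  if (n - k > nrow(endogenous$reads)) stop("not enough endogenous reads")

  take_c <- if (k > 0) sort(sample.int(nrow(contaminant$reads), k)) else integer(0)
  take_e <- if (n - k > 0) {
    sort(sample.int(nrow(endogenous$reads), n - k))
  } else {
    integer(0)
  }
  ## fraction == 0 must return the endogenous set unchanged
  if (fraction == 0) take_e <- seq_len(n)

  reads <- rbind(endogenous$reads[take_e, ], contaminant$reads[take_c, ])
  rownames(reads) <- NULL
  class(reads) <- c("quality_reads", "data.frame")
  truth <- rbind(endogenous$truth[take_e, ], contaminant$truth[take_c, ])
  rownames(truth) <- NULL
  structure(
    list(
      reads = reads, truth = truth,
      params = list(
        endogenous = endogenous$params, contaminant = contaminant$params,
        fraction = fraction, seed = seed
      ),
      genome_length = endogenous$genome_length
    ),
    class = "sim_reads"
  )
}

#' True alignments of simulated reads
#'
#' Converts the simulator's ground truth directly into a [mapped_reads()]
#' table (the placements the simulator used), bypassing the mapper. Useful
#' as an oracle and for profiling damage at scales where running the full
#' mapper is unnecessary: the simulator emits no indels, so every truth
#' alignment is a full-length match at the true coordinates.
#'
#' @param sim a `sim_reads` object.
#' @param ref_id reference name to record.
#' @return a `mapped_reads` data frame.
#' @export
true_alignments <- function(sim, ref_id = "ref") {
  t <- sim$truth
  mapped_reads(
    read_id = t$read_id, ref_id = ref_id, start = t$start,
    strand = t$strand, cigar = paste0(t$length, "M"),
    seq = ifelse(t$strand == "-", revcomp(sim$reads$seq), sim$reads$seq),
    qual = ifelse(t$strand == "-",
      vapply(sim$reads$qual, function(q) {
        intToUtf8(rev(utf8ToInt(q)))
      }, "", USE.NAMES = FALSE),
      sim$reads$qual
    ),
    edit = NA_integer_, score = NA_integer_, unique_best = TRUE
  )
}

#' Write simulator truth to a TSV file
#'
#' @param sim a `sim_reads` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth <- function(sim, file) {
  t <- sim$truth
  t$damage_pos <- vapply(t$damage_pos, paste, "", collapse = ",")
  t$error_pos <- vapply(t$error_pos, paste, "", collapse = ",")
  write.table(t, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
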
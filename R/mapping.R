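#' Mapper parameters
#'
#' Parameters of the built-in seeded, ungapped aligner for small circular
#' references. `min_score_gap` is the uniqueness margin: a placement is
#' `unique_best` only if every alternative placement scores at least
#' `min_score_gap` lower. Retaining only unique-best placements with a
#' bounded mismatch fraction is this package's proxy for a MAPQ >= 30
#' filter (stringency against nuclear mitochondrial insertions, NUMTs).
#'
#' @param k exact seed length (>= 11).
#' @param max_mismatch_frac maximum mismatch fraction for a valid placement.
#' @param band reserved for gapped extension; unused by the ungapped mapper.
#' @param min_score_gap uniqueness margin in score units (1 mismatch = 2).
#' @return a `map_params` list.
#' @export
map_params <- function(k = 13L, max_mismatch_frac = 0.1, band = 0L,
                       min_score_gap = 1L) {
  if (k < 11L) stop("seed length k must be >= 11")
  structure(
    list(
      k = as.integer(k), max_mismatch_frac = max_mismatch_frac,
      band = as.integer(band), min_score_gap = as.integer(min_score_gap)
    ),
    class = "map_params"
  )
}

#' Construct a mapped-read table
#'
#' One row per aligned read. Coordinates are 0-based half-open on the
#' circular reference; `start` is in `[0, L)` and the aligned span may run
#' past `L` (origin wrap). Sequences and qualities are stored
#' reference-oriented (reverse-strand reads are reverse-complemented).
#'
#' @param read_id,ref_id,start,strand,cigar,seq,qual,edit,score,unique_best
#'   per-read fields; `cigar` uses M/I/D operations.
#' @return a `mapped_reads` data frame.
#' @export
mapped_reads <- function(read_id, ref_id, start, strand, cigar, seq, qual,
                         edit, score, unique_best) {
  df <- data.frame(
    read_id = as.character(read_id), ref_id = as.character(ref_id),
    start = as.integer(start), strand = as.character(strand),
    cigar = as.character(cigar), seq = as.character(seq),
    qual = as.character(qual), edit = as.integer(edit),
    score = as.integer(score), unique_best = as.logical(unique_best),
    stringsAsFactors = FALSE
  )
  class(df) <- c("mapped_reads", "data.frame")
  df
}

## Reference span consumed by a CIGAR (M + D).
cigar_ref_span <- function(cigar) {
  ops <- gregexpr("[0-9]+[MID]", cigar)
  vapply(regmatches(cigar, ops), function(x) {
    n <- as.integer(sub("[MID]", "", x))
    op <- substr(x, nchar(x), nchar(x))
    sum(n[op != "I"])
  }, integer(1))
}

## CIGAR -> per-op data frame.
cigar_ops <- function(cigar) {
  x <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  data.frame(
    n = as.integer(sub("[MID]", "", x)),
    op = substr(x, nchar(x), nchar(x))
  )
}

#' Build a k-mer index of a circular reference
#'
#' Linearises the circle with a pad of `max_query_len - 1` bases so any
#' placement, including origin-spanning ones, is a plain substring match.
#'
#' @param ref reference sequence (A/C/G/T string).
#' @param k seed length.
#' @param max_query_len longest query the index must support.
#' @return a `ref_index` list (exported for reuse across many
#'   [map_read()] calls).
#' @export
ref_index <- function(ref, k = 13L, max_query_len = 200L) {
  ref <- toupper(ref)
  L <- nchar(ref)
  pad <- paste0(ref, substr(ref, 1L, max_query_len - 1L))
  kmers <- substring(pad, seq_len(L), seq_len(L) + k - 1L)
  idx <- split(0:(L - 1L), kmers) # 0-based start positions
  structure(
    list(env = list2env(idx, hash = TRUE), ref = ref, pad = pad, L = L, k = k),
    class = "ref_index"
  )
}

## Candidate evaluation: mismatch count of query placed at 0-based pos.
.count_mismatches <- function(pad, pos, query_chars) {
  ref_chars <- utf8ToInt(substr(pad, pos + 1L, pos + length(query_chars)))
  sum(ref_chars != query_chars)
}

## Fast scalar reverse complement (avoids S4 dispatch in hot loops).
.revcomp1 <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANTGCAN", s))))
}

## Core of map_read: returns a plain list (or NULL), no data.frame cost.
.map_one <- function(seq, qual, index, params) {
  len <- nchar(seq)
  if (len < index$k) {
    return(NULL)
  }
  fwd <- toupper(seq)
  rev <- .revcomp1(fwd)
  offsets <- unique(c(seq.int(0L, len - index$k, by = index$k), len - index$k))

  best <- NULL
  second_score <- -Inf
  env <- index$env
  pad <- index$pad
  L <- index$L
  k <- index$k
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else rev
    qchars <- utf8ToInt(s)
    starts <- integer(0)
    for (o in offsets) {
      hit <- env[[substr(s, o + 1L, o + k)]]
      if (!is.null(hit)) starts <- c(starts, (hit - o) %% L)
    }
    for (pos in unique(starts)) {
      mm <- sum(utf8ToInt(substr(pad, pos + 1L, pos + len)) != qchars)
      score <- len - 2L * mm
      if (is.null(best) || score > best$score) {
        if (!is.null(best)) second_score <- max(second_score, best$score)
        best <- list(pos = pos, strand = strand, mm = mm, score = score)
      } else {
        second_score <- max(second_score, score)
      }
    }
  }
  if (is.null(best) || best$mm / len > params$max_mismatch_frac) {
    return(NULL)
  }
  list(
    pos = best$pos, strand = best$strand, mm = best$mm, score = best$score,
    unique_best = (best$score - second_score) >= params$min_score_gap,
    seq = if (best$strand == "+") fwd else rev,
    qual = if (best$strand == "+") qual else intToUtf8(rev(utf8ToInt(qual))),
    len = len
  )
}

#' Map one read to a circular reference
#'
#' Exact k-mer seeding on both strands (non-overlapping seeds plus a final
#' 3'-anchored seed), followed by ungapped evaluation of each candidate
#' placement. The best-scoring placement is returned; `unique_best` is
#' `FALSE` when a runner-up placement scores within `min_score_gap`.
#' Placements whose mismatch fraction exceeds `max_mismatch_frac` are
#' rejected, so reads of ambiguous bases only are simply unmapped.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string.
#' @param index a [ref_index()].
#' @param params a [map_params()].
#' @param read_id identifier to record.
#' @return a one-row [mapped_reads()] table, or `NULL` if unmapped.
#' @export
map_read <- function(seq, qual, index, params = map_params(),
                     read_id = "read") {
  m <- .map_one(seq, qual, index, params)
  if (is.null(m)) {
    return(NULL)
  }
  mapped_reads(
    read_id = read_id, ref_id = "ref", start = m$pos,
    strand = m$strand, cigar = paste0(m$len, "M"), seq = m$seq,
    qual = m$qual, edit = m$mm, score = m$score,
    unique_best = m$unique_best
  )
}

#' Map a read set to one reference
#'
#' @param reads a [quality_reads()] object.
#' @param ref reference sequence (single string) or a [ref_index()].
#' @param params a [map_params()].
#' @param ref_id reference name recorded in the output.
#' @param only_unique drop placements that are not `unique_best` (the
#'   package's MAPQ-style stringency filter; default `TRUE`).
#' @return a [mapped_reads()] table (possibly 0 rows).
#' @export
map_reads <- function(reads, ref, params = map_params(), ref_id = "ref",
                      only_unique = TRUE) {
  idx <- if (inherits(ref, "ref_index")) {
    ref
  } else {
    ref_index(ref, params$k, max_query_len = max(nchar(reads$seq), 200L))
  }
  n <- nrow(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- .map_one(reads$seq[i], reads$qual[i], idx, params)
  }
  hit <- !vapply(out, is.null, logical(1))
  out <- out[hit]
  pick <- function(f, mode) vapply(out, `[[`, vector(mode, 1L), f)
  res <- mapped_reads(
    read_id = reads$read_id[hit], ref_id = rep(ref_id, sum(hit)),
    start = pick("pos", "integer"), strand = pick("strand", "character"),
    cigar = sprintf("%dM", pick("len", "integer")),
    seq = pick("seq", "character"), qual = pick("qual", "character"),
    edit = pick("mm", "integer"), score = pick("score", "integer"),
    unique_best = pick("unique_best", "logical")
  )
  if (only_unique) {
    res <- res[res$unique_best, , drop = FALSE]
    rownames(res) <- NULL
    class(res) <- c("mapped_reads", "data.frame")
  }
  res
}

#' Map against several candidate references and pick the best
#'
#' Maps the full read set independently against every candidate reference;
#' "best" is the reference retaining the most (unique-best, mismatch-
#' filtered) mapped reads, ties broken by lower summed edit distance, then
#' lexicographically by reference id (flagged).
#'
#' @param reads a [quality_reads()] object.
#' @param references named character vector of candidate genomes (>= 2).
#' @param params a [map_params()].
#' @return list with `best_ref`, `tie` (logical), `table` (per-reference
#'   stats, ordered best-first), and `alignments` (the [mapped_reads()]
#'   table for the winning reference).
#' @export
select_best_reference <- function(reads, references, params = map_params()) {
  if (length(references) < 2L) stop("need at least 2 candidate references")
  if (is.null(names(references)) || any(names(references) == "")) {
    stop("references must be named")
  }
  maps <- lapply(names(references), function(rn) {
    map_reads(reads, references[[rn]], params, ref_id = rn)
  })
  names(maps) <- names(references)
  tab <- data.frame(
    ref_id = names(references),
    n_retained = vapply(maps, nrow, integer(1)),
    sum_edit = vapply(maps, function(m) sum(as.numeric(m$edit)), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (all(tab$n_retained == 0L)) stop("no reference compatible")
  ord <- order(-tab$n_retained, tab$sum_edit, tab$ref_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tie <- nrow(tab) > 1L && tab$n_retained[1L] == tab$n_retained[2L] &&
    tab$sum_edit[1L] == tab$sum_edit[2L]
  list(
    best_ref = tab$ref_id[1L], tie = tie, table = tab,
    alignments = maps[[tab$ref_id[1L]]]
  )
}

#' Remove coordinate duplicates
#'
#' Duplicate key is `(ref_id, start, end, strand)`; one representative per
#' key is kept — the read with the highest summed base quality, ties broken
#' by smallest `read_id`. Duplication level = `1 - retained/input`.
#'
#' @param mapped a [mapped_reads()] table (single reference).
#' @return list with `reads` (retained [mapped_reads()]) and `stats`
#'   (`n_in`, `n_retained`, `duplication_level`).
#' @export
deduplicate <- function(mapped) {
  if (!nrow(mapped)) {
    return(list(reads = mapped, stats = list(
      n_in = 0L, n_retained = 0L, duplication_level = NA_real_
    )))
  }
  span <- cigar_ref_span(mapped$cigar)
  key <- paste(mapped$ref_id, mapped$start, mapped$start + span,
    mapped$strand,
    sep = ":"
  )
  sumq <- vapply(mapped$qual, function(q) sum(utf8ToInt(q)), numeric(1),
    USE.NAMES = FALSE
  )
  ord <- order(key, -sumq, mapped$read_id)
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  out <- mapped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mapped_reads", "data.frame")
  list(
    reads = out,
    stats = list(
      n_in = nrow(mapped), n_retained = nrow(out),
      duplication_level = 1 - nrow(out) / nrow(mapped)
    )
  )
}

#' Build a pileup from mapped reads
#'
#' Per reference position: counts of A, C, G, T and deletions; depth is the
#' sum of the four base counts (deletions do not add depth). Insertions
#' consume read bases but no reference positions. Coordinates wrap modulo
#' the reference length.
#'
#' @param mapped a [mapped_reads()] table on one reference.
#' @param ref_length reference length.
#' @return a `pileup` list: `counts` (5 x L matrix, rows A/C/G/T/-) and
#'   `depth` (length-L integer vector).
#' @export
make_pileup <- function(mapped, ref_length) {
  L <- as.integer(ref_length)
  if (length(unique(mapped$ref_id)) > 1L) {
    stop("all reads must be on the same reference")
  }
  counts <- matrix(0L, nrow = 5L, ncol = L,
    dimnames = list(c("A", "C", "G", "T", "-"), NULL)
  )
  if (nrow(mapped)) {
    if (any(mapped$start < 0L | mapped$start >= L)) {
      stop("read start outside [0, reference length)")
    }
    simple <- grepl("^[0-9]+M$", mapped$cigar)
    if (any(simple)) {
      sub <- mapped[simple, , drop = FALSE]
      lens <- nchar(sub$seq)
      pos <- (rep.int(sub$start, lens) + sequence(lens) - 1L) %% L
      base <- match(
        unlist(strsplit(sub$seq, "", fixed = TRUE), use.names = FALSE),
        c("A", "C", "G", "T")
      )
      ok <- !is.na(base) # N bases contribute nothing
      bin <- pos[ok] * 5L + base[ok]
      tab <- tabulate(bin, nbins = 5L * L)
      counts <- counts + matrix(tab, nrow = 5L)
    }
    for (i in which(!simple)) {
      ops <- cigar_ops(mapped$cigar[i])
      rpos <- mapped$start[i]
      qpos <- 1L
      chars <- strsplit(mapped$seq[i], "", fixed = TRUE)[[1]]
      for (j in seq_len(nrow(ops))) {
        n <- ops$n[j]
        if (ops$op[j] == "M") {
          for (t in seq_len(n)) {
            b <- match(chars[qpos + t - 1L], c("A", "C", "G", "T"))
            if (!is.na(b)) {
              col <- (rpos + t - 1L) %% L + 1L
              counts[b, col] <- counts[b, col] + 1L
            }
          }
          rpos <- rpos + n
          qpos <- qpos + n
        } else if (ops$op[j] == "D") {
          cols <- (rpos + seq_len(n) - 1L) %% L + 1L
          counts[5L, cols] <- counts[5L, cols] + 1L
          rpos <- rpos + n
        } else { # I
          qpos <- qpos + n
        }
      }
    }
  }
  structure(
    list(counts = counts, depth = colSums(counts[1:4, , drop = FALSE])),
    class = "pileup"
  )
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf(
    "pileup: %d positions, mean depth %.2f\n",
    length(x$depth), mean(x$depth)
  ))
  invisible(x)
}

#' Write mapped reads to a minimal SAM file
#'
#' Dialect: `@HD`/`@SQ` header, FLAG 0/16, 1-based POS, MAPQ 60 for
#' unique-best placements else 0, CIGAR with M/I/D, SEQ/QUAL reference-
#' oriented, `NM:i` tag. Origin-wrapping alignments are written with their
#' full-length CIGAR at the wrapped POS (documented extension of the
#' dialect for circular references).
#'
#' @param mapped a [mapped_reads()] table.
#' @param file output path.
#' @param ref_length reference length for the `@SQ` line.
#' @return `file`, invisibly.
#' @export
write_sam <- function(mapped, file, ref_length) {
  rn <- unique(mapped$ref_id)
  if (length(rn) != 1L) rn <- rn[1L]
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", rn, as.integer(ref_length))
  )
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
    mapped$read_id, ifelse(mapped$strand == "-", 16L, 0L), mapped$ref_id,
    mapped$start + 1L, ifelse(mapped$unique_best, 60L, 0L), mapped$cigar,
    mapped$seq, mapped$qual, mapped$edit
  )
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' Read a minimal SAM file
#'
#' Parses the dialect written by [write_sam()] (flags 0/16/4; M/I/D CIGARs;
#' optional `NM:i` tag). Unmapped records (flag 4) are skipped.
#'
#' @param file SAM path.
#' @return list with `reads` (a [mapped_reads()] table) and `ref_length`
#'   (from the `@SQ` line, or `NA`).
#' @export
read_sam <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  ref_length <- NA_integer_
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq)) {
    ln <- regmatches(sq[1], regexpr("LN:[0-9]+", sq[1]))
    if (length(ln)) ref_length <- as.integer(sub("LN:", "", ln))
  }
  if (!length(body)) {
    return(list(
      reads = mapped_reads(
        character(0), character(0), integer(0), character(0), character(0),
        character(0), character(0), integer(0), integer(0), logical(0)
      ),
      ref_length = ref_length
    ))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]
  flag <- flag[keep]
  nm <- vapply(f, function(x) {
    t <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("NM:i:", "", t[1])) else NA_integer_
  }, integer(1))
  mq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  list(
    reads = mapped_reads(
      read_id = vapply(f, `[`, "", 1L),
      ref_id = vapply(f, `[`, "", 3L),
      start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
      cigar = vapply(f, `[`, "", 6L),
      seq = vapply(f, `[`, "", 10L),
      qual = vapply(f, `[`, "", 11L),
      edit = nm, score = NA_integer_, unique_best = mq >= 30L
    ),
    ref_length = ref_length
  )
}
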
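DAMAGE_TYPES <- local({
  t <- as.vector(t(outer(
    c("A", "C", "G", "T"), c("A", "C", "G", "T"),
    function(a, b) paste0(a, ">", b)
  )))
  t[substr(t, 1, 1) != substr(t, 3, 3)]
})

## Tally one terminal offset: rb/db are the reference/read bases at this
## offset across reads (read orientation), nix/ndel counts of insertion /
## deletion events at the offset. Returns updated count/opp rows.
.tally_offset <- function(count, opp, o, rb, db, n_ins = 0L, n_del = 0L) {
  for (b in DNA_BASES) {
    nb <- sum(rb == b)
    if (nb) {
      tcols <- DAMAGE_TYPES[startsWith(DAMAGE_TYPES, b)]
      opp[o, tcols] <- opp[o, tcols] + nb
    }
  }
  sel <- rb != db & rb %in% DNA_BASES & db %in% DNA_BASES
  if (any(sel)) {
    tab <- table(paste0(rb[sel], ">", db[sel]))
    count[o, names(tab)] <- count[o, names(tab)] + as.integer(tab)
  }
  opp[o, c("ins", "del")] <- opp[o, c("ins", "del")] + length(rb)
  count[o, "ins"] <- count[o, "ins"] + n_ins
  count[o, "del"] <- count[o, "del"] + n_del
  list(count = count, opp = opp)
}

## Expand one (possibly gapped) alignment into read-oriented columns.
## Returns list(refb, readb, ins) where ins marks an insertion event
## attached to the preceding aligned column.
.aligned_columns <- function(start, cigar, seq, strand, pad) {
  ops <- cigar_ops(cigar)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  refb <- character(0)
  readb <- character(0)
  insv <- logical(0)
  rpos <- start
  qpos <- 1L
  for (j in seq_len(nrow(ops))) {
    n <- ops$n[j]
    op <- ops$op[j]
    if (op == "M") {
      refb <- c(refb, strsplit(substr(pad, rpos + 1L, rpos + n), "")[[1]])
      readb <- c(readb, chars[qpos:(qpos + n - 1L)])
      insv <- c(insv, rep(FALSE, n))
      rpos <- rpos + n
      qpos <- qpos + n
    } else if (op == "D") {
      refb <- c(refb, strsplit(substr(pad, rpos + 1L, rpos + n), "")[[1]])
      readb <- c(readb, rep("-", n))
      insv <- c(insv, rep(FALSE, n))
      rpos <- rpos + n
    } else { # I
      if (length(insv)) insv[length(insv)] <- TRUE
      qpos <- qpos + n
    }
  }
  if (strand == "-") {
    comp <- c(
      A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-"
    )
    refb <- rev(unname(comp[refb]))
    readb <- rev(unname(comp[readb]))
    insv <- rev(insv)
  }
  list(refb = refb, readb = readb, ins = insv)
}

#' Terminal misincorporation and indel profile
#'
#' Computes, for offsets `0 .. n_positions-1` from the 5' end and from the
#' 3' end of each read (in read orientation: reverse-strand alignments are
#' complemented and flipped, so post-mortem deamination appears as C->T at
#' the 5' end and G->A at the 3' end), the frequency of each of the 12
#' substitution types plus insertion and deletion frequencies.
#'
#' Substitution frequencies are conditional on the source base: the
#' denominator of `X>Y` at offset `i` counts reads whose reference base at
#' offset `i` is `X`. Indel denominators count all reads covering the
#' offset. The built-in mapper is ungapped, so indel tracks are non-zero
#' only for alignments imported from SAM. Reads shorter than `n_positions`
#' contribute only their covered offsets.
#'
#' @param mapped a [mapped_reads()] table.
#' @param ref reference sequence (single string).
#' @param n_positions number of terminal offsets to profile (default 25).
#' @return a `damage_profile` list: `freq5`, `freq3` (n_positions x 14
#'   matrices; 12 substitution types plus `ins`/`del`; `NA` where there
#'   were no opportunities), raw `count5`/`opp5`/`count3`/`opp3`, and
#'   `n_reads`. Row `i` is terminal offset `i - 1`.
#' @export
damage_profile <- function(mapped, ref, n_positions = 25L) {
  if (!nrow(mapped)) stop("empty alignment")
  ref <- toupper(ref)
  n_positions <- as.integer(n_positions)
  cols <- c(DAMAGE_TYPES, "ins", "del")
  count5 <- matrix(0, n_positions, length(cols), dimnames = list(NULL, cols))
  opp5 <- count5
  count3 <- count5
  opp3 <- count5

  max_span <- max(cigar_ref_span(mapped$cigar))
  pad <- paste0(ref, substr(ref, 1L, max_span))

  simple <- grepl("^[0-9]+M$", mapped$cigar)

  if (any(simple)) {
    sub <- mapped[simple, , drop = FALSE]
    lens <- nchar(sub$seq)
    rref <- substring(pad, sub$start + 1L, sub$start + lens)
    rseq <- sub$seq
    neg <- sub$strand == "-"
    if (any(neg)) {
      rref[neg] <- revcomp(rref[neg])
      rseq[neg] <- revcomp(rseq[neg])
    }
    for (o in seq_len(n_positions)) {
      cov <- lens >= o
      if (!any(cov)) break
      rb <- substring(rref[cov], o, o)
      db <- substring(rseq[cov], o, o)
      r <- .tally_offset(count5, opp5, o, rb, db)
      count5 <- r$count
      opp5 <- r$opp
      p3 <- lens[cov] - o + 1L
      rb <- substring(rref[cov], p3, p3)
      db <- substring(rseq[cov], p3, p3)
      r <- .tally_offset(count3, opp3, o, rb, db)
      count3 <- r$count
      opp3 <- r$opp
    }
  }

  for (i in which(!simple)) {
    ac <- .aligned_columns(
      mapped$start[i], mapped$cigar[i], mapped$seq[i], mapped$strand[i], pad
    )
    ncols <- length(ac$refb)
    for (o in seq_len(min(n_positions, ncols))) {
      r <- .tally_offset(
        count5, opp5, o, ac$refb[o], ac$readb[o],
        n_ins = as.integer(ac$ins[o]),
        n_del = as.integer(ac$readb[o] == "-")
      )
      count5 <- r$count
      opp5 <- r$opp
      o3 <- ncols - o + 1L
      r <- .tally_offset(
        count3, opp3, o, ac$refb[o3], ac$readb[o3],
        n_ins = as.integer(ac$ins[o3]),
        n_del = as.integer(ac$readb[o3] == "-")
      )
      count3 <- r$count
      opp3 <- r$opp
    }
  }

  ## a deleted column has no read base, so remove it from substitution
  ## opportunity bookkeeping is not needed: opportunities count reference
  ## bases, deletions included by design (documented).
  freq5 <- count5 / ifelse(opp5 > 0, opp5, NA)
  freq3 <- count3 / ifelse(opp3 > 0, opp3, NA)
  structure(
    list(
      freq5 = freq5, freq3 = freq3,
      count5 = count5, opp5 = opp5, count3 = count3, opp3 = opp3,
      n_positions = n_positions, n_reads = nrow(mapped)
    ),
    class = "damage_profile"
  )
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf(
    paste0(
      "damage_profile over %d reads: 5' C>T at offset 0 = %.4f, ",
      "3' G>A at offset 0 = %.4f\n"
    ),
    x$n_reads, x$freq5[1, "C>T"], x$freq3[1, "G>A"]
  ))
  invisible(x)
}

#' Export a damage profile as a tidy table
#'
#' @param x a `damage_profile`.
#' @param ... unused.
#' @return data frame with columns `end` (`"5p"`/`"3p"`), `offset`
#'   (0-based), `type`, `count`, `opportunities`, `frequency`.
#' @export
as.data.frame.damage_profile <- function(x, ...) {
  mk <- function(end, count, opp, freq) {
    data.frame(
      end = end,
      offset = rep(seq_len(nrow(count)) - 1L, ncol(count)),
      type = rep(colnames(count), each = nrow(count)),
      count = as.vector(count),
      opportunities = as.vector(opp),
      frequency = as.vector(freq)
    )
  }
  rbind(
    mk("5p", x$count5, x$opp5, x$freq5),
    mk("3p", x$count3, x$opp3, x$freq3)
  )
}
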
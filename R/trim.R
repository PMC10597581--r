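#' Quality-trimming configuration
#'
#' Defaults reproduce the study-style Trimmomatic invocation
#' `MINLEN:30 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 AVGQUAL:30`,
#' including its printed (unusual) step order with MINLEN first. The order
#' is configurable via `step_order`.
#'
#' @param leading_q Phred threshold for LEADING (5' end clipping).
#' @param trailing_q Phred threshold for TRAILING (3' end clipping).
#' @param window_len,window_q sliding-window length and mean-quality
#'   threshold.
#' @param min_len minimum read length after trimming.
#' @param min_avg_q minimum mean read quality.
#' @param step_order character vector over
#'   `c("MINLEN","SLIDINGWINDOW","LEADING","TRAILING","AVGQUAL")`.
#' @return a `trim_config` list.
#' @export
trim_config <- function(leading_q = 20L, trailing_q = 20L, window_len = 4L,
                        window_q = 20L, min_len = 30L, min_avg_q = 30L,
                        step_order = c(
                          "MINLEN", "SLIDINGWINDOW", "LEADING",
                          "TRAILING", "AVGQUAL"
                        )) {
  known <- c("MINLEN", "SLIDINGWINDOW", "LEADING", "TRAILING", "AVGQUAL")
  if (!all(step_order %in% known) || anyDuplicated(step_order)) {
    stop(
      "step_order must be a permutation of a subset of: ",
      paste(known, collapse = ", ")
    )
  }
  structure(
    list(
      leading_q = as.integer(leading_q), trailing_q = as.integer(trailing_q),
      window_len = as.integer(window_len), window_q = as.integer(window_q),
      min_len = as.integer(min_len), min_avg_q = as.integer(min_avg_q),
      step_order = step_order
    ),
    class = "trim_config"
  )
}

## Single-step primitives on an integer quality vector; each returns the
## surviving index range relative to its input (integer(0) = all removed).
.trim_leading <- function(q, thr) {
  bad <- q < thr
  first <- which(!bad)
  if (!length(first)) {
    return(integer(0))
  }
  seq.int(first[1L], length(q))
}

.trim_trailing <- function(q, thr) {
  last <- which(q >= thr)
  if (!length(last)) {
    return(integer(0))
  }
  seq.int(1L, last[length(last)])
}

## Scan complete windows 5'->3'; truncate at the start of the first window
## whose arithmetic mean quality is below thr. Reads shorter than the window
## are left untouched. Mean is exact (no rounding before comparison).
.trim_window <- function(q, len, thr) {
  n <- length(q)
  if (n < len) {
    return(seq_len(n))
  }
  cs <- cumsum(c(0, q))
  means <- (cs[(len + 1L):(n + 1L)] - cs[1L:(n - len + 1L)]) / len
  bad <- which(means < thr)
  if (!length(bad)) {
    return(seq_len(n))
  }
  seq_len(bad[1L] - 1L)
}

## Full trimming record for one read: surviving [lo, hi] window (hi < lo =
## discarded/empty), the step that discarded it, and per-step base losses.
.trim_read_full <- function(q, cfg) {
  lo <- 1L
  hi <- length(q)
  losses <- setNames(integer(length(cfg$step_order)), cfg$step_order)
  for (step in cfg$step_order) {
    n <- hi - lo + 1L
    if (n <= 0L) {
      return(list(lo = lo, hi = hi, discarded_by = step, losses = losses))
    }
    cur <- q[lo:hi]
    if (step == "MINLEN") {
      if (n < cfg$min_len) {
        return(list(lo = 1L, hi = 0L, discarded_by = step, losses = losses))
      }
    } else if (step == "AVGQUAL") {
      if (mean(cur) < cfg$min_avg_q) {
        return(list(lo = 1L, hi = 0L, discarded_by = step, losses = losses))
      }
    } else {
      idx <- switch(step,
        LEADING = .trim_leading(cur, cfg$leading_q),
        TRAILING = .trim_trailing(cur, cfg$trailing_q),
        SLIDINGWINDOW = .trim_window(cur, cfg$window_len, cfg$window_q)
      )
      losses[step] <- n - length(idx)
      if (!length(idx)) {
        return(list(
          lo = 1L, hi = 0L, discarded_by = step,
          losses = losses
        ))
      }
      hi <- lo + idx[length(idx)] - 1L
      lo <- lo + idx[1L] - 1L
    }
  }
  list(lo = lo, hi = hi, discarded_by = NA_character_, losses = losses)
}

#' Trim a single read
#'
#' Applies the configured steps in `cfg$step_order`: LEADING/TRAILING clip
#' low-quality bases from the ends, SLIDINGWINDOW truncates at the start of
#' the first length-`window_len` window whose mean quality falls below
#' `window_q`, MINLEN and AVGQUAL discard the read outright. An empty input
#' read is a discard, not an error. The output is always a contiguous
#' substring of the input.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string (same length).
#' @param cfg a [trim_config()].
#' @return `list(seq=, qual=)` of the surviving substring, or `NULL` if the
#'   read is discarded.
#' @export
trim_read <- function(seq, qual, cfg = trim_config()) {
  if (nchar(seq) != nchar(qual)) stop("sequence/quality length mismatch")
  r <- .trim_read_full(phred_decode(qual), cfg)
  if (r$hi < r$lo) {
    return(NULL)
  }
  list(seq = substr(seq, r$lo, r$hi), qual = substr(qual, r$lo, r$hi))
}

#' Trim a read set
#'
#' Order-preserving application of [trim_read()] with summary statistics.
#'
#' @param reads a [quality_reads()] object.
#' @param cfg a [trim_config()].
#' @return list with `reads` (kept, trimmed) and `stats` (`trim_stats`:
#'   `n_in`, `n_kept`, `survival_fraction`, per-step read discards and base
#'   losses).
#' @export
trim_set <- function(reads, cfg = trim_config()) {
  n <- nrow(reads)
  keep <- logical(n)
  oseq <- character(n)
  oqual <- character(n)
  base_loss <- setNames(numeric(length(cfg$step_order)), cfg$step_order)
  discards <- setNames(
    integer(length(cfg$step_order)), cfg$step_order
  )
  for (i in seq_len(n)) {
    r <- .trim_read_full(phred_decode(reads$qual[i]), cfg)
    base_loss <- base_loss + r$losses[names(base_loss)]
    if (r$hi < r$lo) {
      discards[r$discarded_by] <- discards[r$discarded_by] + 1L
    } else {
      keep[i] <- TRUE
      oseq[i] <- substr(reads$seq[i], r$lo, r$hi)
      oqual[i] <- substr(reads$qual[i], r$lo, r$hi)
    }
  }
  kept <- quality_reads(
    reads$read_id[keep], oseq[keep], oqual[keep],
    source = if (!is.null(reads$source)) reads$source[keep]
  )
  stats <- structure(
    list(
      n_in = n, n_kept = sum(keep),
      survival_fraction = if (n) sum(keep) / n else NA_real_,
      reads_discarded_by_step = discards,
      bases_removed_by_step = base_loss
    ),
    class = "trim_stats"
  )
  list(reads = kept, stats = stats)
}

#' @export
print.trim_stats <- function(x, ...) {
  cat(sprintf(
    "trim_stats: %d/%d reads kept (%.1f%% survival)\n",
    x$n_kept, x$n_in, 100 * x$survival_fraction
  ))
  invisible(x)
}
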
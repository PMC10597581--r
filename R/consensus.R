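#' Call a consensus sequence from a pileup
#'
#' Per position the base with the highest count wins; positions with depth
#' below `min_depth` and ties among top counts are set to `N` (ambiguity
#' codes are deliberately not used: downstream diagnostic-site logic treats
#' `N` as missing).
#'
#' @param pileup a [make_pileup()] result.
#' @param min_depth minimum depth to call a base (default 2).
#' @return a `consensus_result` list: `seq` (string over A/C/G/T/N),
#'   `depth`, `stats` (a `coverage_stats` list), `min_depth`.
#' @export
call_consensus <- function(pileup, min_depth = 2L) {
  counts <- pileup$counts[1:4, , drop = FALSE]
  depth <- pileup$depth
  top <- apply(counts, 2L, max)
  winner <- max.col(t(counts), ties.method = "first")
  n_top <- colSums(counts == rep(top, each = 4L) & counts > 0L)
  base <- DNA_BASES[winner]
  base[n_top != 1L | depth < min_depth] <- "N"
  seq <- paste(base, collapse = "")
  structure(
    list(
      seq = seq, depth = depth,
      stats = coverage_stats(depth, seq), min_depth = as.integer(min_depth)
    ),
    class = "consensus_result"
  )
}

#' Depth and breadth statistics
#'
#' Mean depth is the sum of per-position depth divided by the genome
#' length; breadth at `k` is the fraction of positions with depth >= `k`.
#'
#' @param depth integer vector of per-position depth.
#' @param consensus optional consensus string for the undetermined (`N`)
#'   fraction.
#' @return a `coverage_stats` list: `mean_depth`, `breadth` (named vector
#'   for k = 1, 2, 3), `undetermined_fraction`.
#' @export
coverage_stats <- function(depth, consensus = NULL) {
  undet <- if (is.null(consensus)) {
    NA_real_
  } else {
    lengths(regmatches(consensus, gregexpr("N", consensus))) / nchar(consensus)
  }
  structure(
    list(
      mean_depth = sum(depth) / length(depth),
      breadth = vapply(
        c(`1` = 1L, `2` = 2L, `3` = 3L),
        function(k) mean(depth >= k), numeric(1)
      ),
      undetermined_fraction = undet
    ),
    class = "coverage_stats"
  )
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf(
    "coverage_stats: mean depth %.2fx, breadth 1x/2x/3x = %.3f/%.3f/%.3f\n",
    x$mean_depth, x$breadth[1], x$breadth[2], x$breadth[3]
  ))
  invisible(x)
}

#' Retention QC for a consensus mitogenome
#'
#' A genome is retained only if at least `breadth3_min` of the reference is
#' covered at 3x or more.
#'
#' @param consensus a [call_consensus()] result.
#' @param breadth3_min minimum breadth at 3x (default 0.80).
#' @return list with `retained` (logical) and `reasons` (character vector
#'   of failed criteria, empty when retained).
#' @export
qc_retain <- function(consensus, breadth3_min = 0.80) {
  reasons <- character(0)
  if (consensus$stats$breadth[3] < breadth3_min) {
    reasons <- c(reasons, "breadth3")
  }
  list(retained = length(reasons) == 0L, reasons = reasons)
}

#' GC content of a sequence, excluding N
#'
#' @param sequence a DNA string over A/C/G/T/N.
#' @return `(G + C) / (A + C + G + T)`.
#' @export
gc_content <- function(sequence) {
  if (!nchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- sum(chars %in% DNA_BASES)
  if (n == 0L) stop("sequence has no determined (A/C/G/T) bases")
  sum(chars %in% c("G", "C")) / n
}
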
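#' @importFrom stats runif rlnorm median quantile setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; accepts A/C/G/T/N (case-insensitive, returned upper
#' case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 <-> integer quality helpers (kept internal; qualities are stored
## as encoded strings so reads are FASTQ-ready without conversion).
phred_decode <- function(q) utf8ToInt(q) - 33L

phred_encode <- function(q) intToUtf8(q + 33L)

#' Derive a per-stage seed from a global seed
#'
#' Stable, stage-name-keyed fan-out so each pipeline stage is individually
#' reproducible from one global seed. The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 12345) %% 2147483646 + 1)
}

## Split equal-length sequences into a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must have equal length")
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  rownames(m) <- names(seqs)
  m
}

## Collapse a character matrix back to sequences.
matrix_seq <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

## Circular substring: 0-based start, length len, on genome of length L.
## Returns list(seq, wrap). Vectorised.
circular_substr <- function(genome, start, len) {
  L <- nchar(genome)
  pad <- paste0(genome, substr(genome, 1L, max(len)))
  list(
    seq = substring(pad, start + 1L, start + len),
    wrap = (start + len) > L
  )
}
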
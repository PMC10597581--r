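#' Construct a set of quality reads
#'
#' The basic read container used throughout the pipeline: a data frame with
#' one row per read and columns `read_id`, `seq` (A/C/G/T/N) and `qual`
#' (Phred+33 encoded string, same length as `seq`). An optional `source`
#' column carries a provenance label (e.g. `"endogenous"` or
#' `"contaminant"`).
#'
#' @param read_id character vector of unique read identifiers.
#' @param seq character vector of read sequences.
#' @param qual character vector of Phred+33 quality strings.
#' @param source optional character vector of provenance labels.
#' @return a `quality_reads` data frame.
#' @export
quality_reads <- function(read_id, seq, qual, source = NULL) {
  stopifnot(
    length(read_id) == length(seq), length(seq) == length(qual),
    !anyDuplicated(read_id)
  )
  if (any(nchar(seq) != nchar(qual))) {
    stop("quality string length must equal sequence length")
  }
  df <- data.frame(
    read_id = as.character(read_id), seq = as.character(seq),
    qual = as.character(qual), stringsAsFactors = FALSE
  )
  if (!is.null(source)) df$source <- as.character(source)
  class(df) <- c("quality_reads", "data.frame")
  df
}

#' @export
print.quality_reads <- function(x, ...) {
  cat(sprintf(
    "quality_reads: %d reads, length %s\n", nrow(x),
    if (nrow(x)) paste0(min(nchar(x$seq)), "-", max(nchar(x$seq))) else "-"
  ))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads a `quality_reads` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fastq <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x,
    filepath = file, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(file)
}

#' Read a FASTQ file (Phred+33) into a quality_reads object
#'
#' @param file FASTQ path.
#' @return a `quality_reads` object.
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq", with.qualities = TRUE)
  quality_reads(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = file)
  invisible(file)
}

#' Read a FASTA file into a named character vector
#'
#' @param file FASTA path.
#' @return named character vector (upper case).
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(toupper(as.character(x)), names(x))
}
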
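# shared low-level helpers

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet matchPattern getGeneticCode
#' @importFrom stats rpois rbinom runif fisher.test pbinom quantile setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# coerce alignment input (named character vector, DNAStringSet, or character
# matrix) to a taxa x columns matrix of single characters
as_aln_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(x)
  }
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x), !is.null(names(x)))
  n <- nchar(x)
  if (length(unique(n)) != 1L)
    stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector, the representation used throughout this package.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
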
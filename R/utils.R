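# Small shared sequence helpers.

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A,C,G,T,N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Accept either a read_fasta() data frame or a named character vector and
# return a named character vector of sequences.
as_named_seqs <- function(x) {
  if (is.data.frame(x)) return(stats::setNames(x$sequence, x$id))
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a read_fasta() data frame or a named character vector")
}

# Longest run of TRUE in a logical vector.
longest_run <- function(ok) {
  if (!any(ok)) return(0L)
  r <- rle(ok)
  max(r$lengths[r$values])
}
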
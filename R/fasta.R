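#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]. Sequence names are
#' truncated at the first whitespace, matching common aligner behaviour.
#' Case is preserved (softmasking is treated as metadata, not sequence).
#'
#' @param path Path to a (possibly wrapped) multi-record FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out))) {
    stop("duplicate sequence ids in ", path)
  }
  if (any(nchar(out) < 1)) stop("empty sequence record in ", path)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement nucleotide sequences
#'
#' IUPAC ambiguity codes are handled; case is preserved.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Extract a 0-based half-open substring of a sequence
#' @noRd
seq_slice <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

#' Lengths of a named sequence set as a lookup vector
#' @noRd
seq_lens <- function(seqs) {
  stats::setNames(nchar(seqs), names(seqs))
}
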
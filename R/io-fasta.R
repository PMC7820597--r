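# FASTA I/O via Biostrings, with the module's stricter validation on top.

#' Read a FASTA file into a named character vector
#'
#' Ids are kept up to the first whitespace and sequences are uppercased.
#' Duplicate ids and non-IUPAC characters are rejected.
#'
#' @param file path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  if (length(ss) == 0L) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("integrity error: duplicate FASTA id '",
         ids[duplicated(ids)][1L], "'")
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("parse error: non-IUPAC character in sequence '",
         ids[grepl("[^ACGTN]", seqs)][1L], "'")
  setNames(unname(seqs), ids)
}

#' Write a named set of sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @param width line-wrap width in columns.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 70L) {
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, file, width = as.integer(width))
  invisible(file)
}
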
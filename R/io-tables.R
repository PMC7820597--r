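# Tabular I/O: the simplified paired-alignment format and count tables.
# Every emitted table starts with a '#'-prefixed header line.

.aln_cols <- c("pair_id", "sample", "contig", "strand", "blocks", "n_hits",
               "both_ends_aligned", "same_contig_strand")

#' Read paired-alignment records from TSV
#'
#' One row per genomic placement of a read pair; multi-mapped pairs have
#' several rows sharing `pair_id` and `n_hits` equals the number of
#' placements. `blocks` holds both mates' aligned blocks as
#' `start-end` pairs (0-based half-open) joined by `;`.
#'
#' @param file path to the alignment TSV.
#' @return data.frame with columns pair_id, sample, contig, strand, blocks,
#'   n_hits, both_ends_aligned, same_contig_strand.
#' @export
read_alignments <- function(file) {
  df <- read.table(file, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = .aln_cols, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character", "character", "integer",
                                  "logical", "logical"))
  if (any(df$n_hits < 1L))
    stop("integrity error: n_hits < 1 in alignment table")
  if (any(df$both_ends_aligned & !nzchar(df$blocks)))
    stop("integrity error: aligned pair without blocks")
  df
}

#' Write paired-alignment records as TSV
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_alignments <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.aln_cols, collapse = "\t")), con)
  write.table(aln[, .aln_cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# parse "s-e;s-e" into a 2-col matrix (0-based half-open)
parse_blocks <- function(blocks) {
  lapply(strsplit(blocks, ";", fixed = TRUE), function(b) {
    if (length(b) == 0L || identical(b, ""))
      return(.as_interval_matrix(matrix(numeric(0), ncol = 2)))
    p <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
    .as_interval_matrix(cbind(as.numeric(p[, 1L]), as.numeric(p[, 2L])))
  })
}

format_blocks <- function(block_list) {
  vapply(block_list, function(b)
    paste(sprintf("%d-%d", as.integer(b[, 1L]), as.integer(b[, 2L])),
          collapse = ";"), "")
}

#' Write a count matrix as TSV
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @param file output path.
#' @param id_col name of the row-identifier column.
#' @return `file`, invisibly.
#' @export
write_count_table <- function(counts, file, id_col = "gene_id") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", id_col, "\t",
                    paste(colnames(counts), collapse = "\t")), con)
  write.table(data.frame(id = rownames(counts), counts,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a count matrix written by [write_count_table()]
#' @param file path to the TSV.
#' @return numeric matrix with row and column names.
#' @export
read_count_table <- function(file) {
  header <- sub("^#", "", readLines(file, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  df <- read.table(file, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- cols[-1L]
  if (any(m < 0)) stop("integrity error: negative counts")
  m
}
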
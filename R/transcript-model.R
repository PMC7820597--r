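#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom rnbinom rpois setNames
#'   p.adjust pnorm phyper var sd glm.fit ave
#' @importFrom utils head tail write.table read.table
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# All external GTF/GFF text is 1-based inclusive; conversion happens only in
# the io layer.

#' Construct a transcript model
#'
#' A transcript model is a stranded chain of exons on one contig, with an
#' optional CDS sub-interval list. All coordinates are 0-based half-open.
#'
#' @param transcript_id,gene_id character identifiers.
#' @param contig contig (chromosome/scaffold) name.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param exons two-column integer matrix of exon `start`,`end` pairs,
#'   0-based half-open; rows are sorted by start and must not overlap.
#' @param cds optional two-column matrix of CDS segments, each contained in
#'   the exon union.
#' @param attributes named character vector of free-form GTF attributes.
#' @return an object of class `"transcript_model"`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand = "+",
                             exons, cds = NULL, attributes = character()) {
  exons <- .as_interval_matrix(exons)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (!is.null(cds)) {
    cds <- .as_interval_matrix(cds)
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
  }
  m <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         contig = as.character(contig),
         strand = strand,
         exons = exons,
         cds = cds,
         attributes = attributes),
    class = "transcript_model")
  validate_transcript_model(m)
  m
}

.as_interval_matrix <- function(x) {
  x <- matrix(as.numeric(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  storage.mode(x) <- "double"
  x
}

#' Validate transcript model invariants
#'
#' Checks start < end per exon, non-overlapping sorted exons, a single
#' contig/strand, and CDS containment within the exon union. Violations
#' raise an integrity error; records are never silently repaired.
#'
#' @param m a `transcript_model`.
#' @return `m`, invisibly.
#' @export
validate_transcript_model <- function(m) {
  ex <- m$exons
  if (nrow(ex) == 0L)
    stop("integrity error: transcript '", m$transcript_id, "' has no exons")
  if (any(ex[, 2L] <= ex[, 1L]))
    stop("integrity error: exon with start >= end in transcript '",
         m$transcript_id, "'")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
    stop("integrity error: overlapping or unsorted exons in transcript '",
         m$transcript_id, "'")
  if (!m$strand %in% c("+", "-", "."))
    stop("integrity error: bad strand '", m$strand, "' in transcript '",
         m$transcript_id, "'")
  if (!nzchar(m$contig))
    stop("integrity error: empty contig in transcript '", m$transcript_id, "'")
  if (!is.null(m$cds) && nrow(m$cds) > 0L) {
    for (i in seq_len(nrow(m$cds))) {
      seg <- m$cds[i, ]
      inside <- any(ex[, 1L] <= seg[1L] & seg[2L] <= ex[, 2L])
      if (!inside)
        stop("integrity error: CDS segment outside exons in transcript '",
             m$transcript_id, "'")
    }
  }
  invisible(m)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s %d exon(s), %d bp spliced%s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), tx_spliced_length(x),
              if (is.null(x$cds)) "" else ", with CDS"))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param m a `transcript_model`.
#' @return total exonic length in bp.
#' @export
tx_spliced_length <- function(m) sum(m$exons[, 2L] - m$exons[, 1L])

#' Intron junctions of a transcript model
#'
#' @param m a `transcript_model`.
#' @return a two-column matrix of intron `(start, end)` coordinates
#'   (0-based half-open, genome order); zero rows for single-exon models.
#' @export
tx_junctions <- function(m) {
  ex <- m$exons
  n <- nrow(ex)
  if (n < 2L) return(.as_interval_matrix(matrix(numeric(0), ncol = 2L)))
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

# genomic span of a model: c(start, end)
tx_span <- function(m) c(m$exons[1L, 1L], m$exons[nrow(m$exons), 2L])

# junction keys as strings "start-end" for set comparisons
tx_junction_keys <- function(m) {
  j <- tx_junctions(m)
  if (nrow(j) == 0L) return(character(0))
  paste0(j[, 1L], "-", j[, 2L])
}

# ordered intron chain as one string (empty for single-exon)
tx_chain_key <- function(m) paste(tx_junction_keys(m), collapse = ";")

#' Genomic span of each gene in a model list
#'
#' The gene span is the union over its isoforms' genomic extents.
#'
#' @param models list of `transcript_model`.
#' @return data.frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @export
gene_spans <- function(models) {
  if (length(models) == 0L)
    return(data.frame(gene_id = character(0), contig = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  gid <- vapply(models, `[[`, "", "gene_id")
  ctg <- vapply(models, `[[`, "", "contig")
  std <- vapply(models, `[[`, "", "strand")
  sp <- t(vapply(models, tx_span, numeric(2)))
  agg <- lapply(split(seq_along(models), gid), function(ix) {
    if (length(unique(ctg[ix])) != 1L)
      stop("integrity error: gene '", gid[ix[1L]], "' spans multiple contigs")
    data.frame(gene_id = gid[ix[1L]], contig = ctg[ix[1L]],
               strand = std[ix[1L]], start = min(sp[ix, 1L]),
               end = max(sp[ix, 2L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Transcript and gene ids of a model list
#' @param models list of `transcript_model`.
#' @return character vector of ids, in list order.
#' @export
model_ids <- function(models) vapply(models, `[[`, "", "transcript_id")

#' @rdname model_ids
#' @export
model_genes <- function(models) vapply(models, `[[`, "", "gene_id")

# GRanges of all exons of a model list, with transcript/gene metadata
models_exon_granges <- function(models) {
  if (length(models) == 0L) {
    return(GenomicRanges::GRanges())
  }
  nex <- vapply(models, function(m) nrow(m$exons), 0L)
  starts <- unlist(lapply(models, function(m) m$exons[, 1L]))
  ends <- unlist(lapply(models, function(m) m$exons[, 2L]))
  GenomicRanges::GRanges(
    seqnames = rep(vapply(models, `[[`, "", "contig"), nex),
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    strand = rep(vapply(models, `[[`, "", "strand"), nex),
    transcript_id = rep(model_ids(models), nex),
    gene_id = rep(model_genes(models), nex))
}

#' Extract the spliced sequence of a transcript model
#'
#' Concatenates exon sequences in genome order and reverse-complements for
#' minus-strand models, so the result reads 5' to 3'.
#'
#' @param m a `transcript_model`.
#' @param genome a named character vector or list of contig sequences.
#' @return the spliced transcript sequence (character scalar).
#' @export
tx_sequence <- function(m, genome) {
  s <- genome[[m$contig]]
  if (is.null(s)) stop("integrity error: contig '", m$contig,
                       "' absent from genome")
  parts <- substring(s, m$exons[, 1L] + 1L, m$exons[, 2L])
  seq <- paste(parts, collapse = "")
  if (m$strand == "-") seq <- revcomp(seq)
  seq
}

#' Reverse-complement a nucleotide string
#' @param x character vector of sequences over A,C,G,T,N.
#' @return reverse complement(s).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
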
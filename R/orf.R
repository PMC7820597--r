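# ORF discovery and completeness typing. For each reading frame the
# maximal ORF of each stop-delimited segment is reported:
#   complete       ATG ... stop
#   5prime_partial sequence start ... stop, no in-frame ATG upstream
#   3prime_partial ATG ... sequence end, no stop
#   internal       frame open across the whole sequence
# aa_length counts codons excluding the stop.

.completeness_rank <- c(complete = 4L, "5prime_partial" = 3L,
                        "3prime_partial" = 2L, internal = 1L)

.empty_orf_df <- function() {
  data.frame(frame = integer(0), strand = character(0), start = integer(0),
             end = integer(0), aa_length = integer(0),
             completeness = character(0), stringsAsFactors = FALSE)
}

#' Find open reading frames in a nucleotide sequence
#'
#' @param seq a single nucleotide string over A,C,G,T,N (case-insensitive).
#' @param min_aa minimum ORF length in codons, excluding the stop codon.
#' @param strands `"forward"` to scan the three forward frames (oriented
#'   transcripts), `"both"` to also scan the reverse complement
#'   (orientation-unknown contigs).
#' @return data.frame with columns `frame` (0,1,2), `strand`, `start`,
#'   `end` (0-based half-open positions on the scanned strand's sequence;
#'   for `strand == "-"` they refer to the reverse complement), `aa_length`
#'   and `completeness`.
#' @export
find_orfs <- function(seq, min_aa = 100L, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (length(seq) != 1L) stop("find_orfs() scans a single sequence")
  if (!nzchar(seq)) return(.empty_orf_df())
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("parse error: character outside {A,C,G,T,N}")
  out <- .scan_frames(seq, min_aa, "+")
  if (strands == "both")
    out <- rbind(out, .scan_frames(revcomp(seq), min_aa, "-"))
  rownames(out) <- NULL
  out
}

.scan_frames <- function(seq, min_aa, strand) {
  L <- nchar(seq)
  res <- .empty_orf_df()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 1L) next
    at <- f + 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(seq, at, at + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    stops <- which(is_stop)
    seg_bounds <- cbind(c(1L, stops + 1L), c(stops, n_cod))
    for (k in seq_len(nrow(seg_bounds))) {
      a <- seg_bounds[k, 1L]; b <- seg_bounds[k, 2L]
      if (a > b) next
      ends_in_stop <- k <= length(stops)
      atg_in <- which(is_atg[a:b])
      first_atg <- if (length(atg_in)) a + atg_in[1L] - 1L else NA_integer_
      if (ends_in_stop) {
        if (!is.na(first_atg) && first_atg < b) {
          aa <- b - first_atg
          if (aa >= min_aa)
            res <- rbind(res, data.frame(
              frame = f, strand = strand,
              start = f + (first_atg - 1L) * 3L, end = f + b * 3L,
              aa_length = aa, completeness = "complete",
              stringsAsFactors = FALSE))
        } else if (a == 1L && is.na(first_atg)) {
          aa <- b - a
          if (aa >= min_aa)
            res <- rbind(res, data.frame(
              frame = f, strand = strand, start = f, end = f + b * 3L,
              aa_length = aa, completeness = "5prime_partial",
              stringsAsFactors = FALSE))
        }
      } else {
        if (!is.na(first_atg)) {
          aa <- b - first_atg + 1L
          if (aa >= min_aa)
            res <- rbind(res, data.frame(
              frame = f, strand = strand,
              start = f + (first_atg - 1L) * 3L, end = f + b * 3L,
              aa_length = aa, completeness = "3prime_partial",
              stringsAsFactors = FALSE))
        } else if (a == 1L) {
          aa <- b
          if (aa >= min_aa)
            res <- rbind(res, data.frame(
              frame = f, strand = strand, start = f, end = f + b * 3L,
              aa_length = aa, completeness = "internal",
              stringsAsFactors = FALSE))
        }
      }
    }
  }
  res
}

#' Assign a single completeness label to a sequence
#'
#' When a sequence carries several ORF types the most complete one wins,
#' under the order complete > 5'-partial > 3'-partial > internal (the
#' preference of 5'- over 3'-partial is a fixed package convention).
#'
#' @param calls data.frame from [find_orfs()] for one sequence.
#' @return a completeness label, or `NA_character_` when there are no
#'   calls.
#' @export
assign_contig_completeness <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) return(NA_character_)
  names(which.max(.completeness_rank[calls$completeness]))
}

# best ORF of a set of calls: highest completeness, then longest
.best_orf <- function(calls) {
  if (nrow(calls) == 0L) return(NULL)
  ord <- order(-.completeness_rank[calls$completeness], -calls$aa_length)
  calls[ord[1L], , drop = FALSE]
}

# best ORF across the transcripts of one gene (forward scan, oriented)
.gene_best_orf <- function(models, genome, min_aa) {
  best <- NULL
  for (m in models) {
    calls <- find_orfs(tx_sequence(m, genome), min_aa = min_aa,
                       strands = "forward")
    b <- .best_orf(calls)
    if (is.null(b)) next
    if (is.null(best) ||
        .completeness_rank[b$completeness] >
        .completeness_rank[best$completeness] ||
        (.completeness_rank[b$completeness] ==
         .completeness_rank[best$completeness] &&
         b$aa_length > best$aa_length))
      best <- b
  }
  best
}

#' Account CDS improvements of an updated annotation
#'
#' Compares, per gene, the best ORF of the reference transcripts to the
#' best ORF of the improved transcripts and reports what was gained:
#' `gained_start` (reference lacked the start codon, improved has an
#' in-frame ATG), `gained_stop` (reference lacked a stop, improved has
#' one), `new_complete` (reference had no ORF of at least `min_aa`
#' codons, improved has a complete one), or `unchanged`.
#'
#' @param reference_models,improved_models lists of transcript models
#'   sharing gene ids.
#' @param genome contig sequences both annotations refer to.
#' @param min_aa minimum reportable ORF length in codons.
#' @return data.frame with columns `gene_id`, `ref_completeness`,
#'   `improved_completeness`, `gained_start`, `gained_stop`,
#'   `new_complete`, `category`.
#' @export
cds_improvement_report <- function(reference_models, improved_models, genome,
                                   min_aa = 100L) {
  ref_by_gene <- split(reference_models, model_genes(reference_models))
  imp_by_gene <- split(improved_models, model_genes(improved_models))
  genes <- intersect(names(ref_by_gene), names(imp_by_gene))
  empty <- data.frame(
    gene_id = character(0), ref_completeness = character(0),
    improved_completeness = character(0), gained_start = logical(0),
    gained_stop = logical(0), new_complete = logical(0),
    category = character(0), stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(empty)
  rows <- lapply(genes, function(g) {
    rb <- .gene_best_orf(ref_by_gene[[g]], genome, min_aa)
    ib <- .gene_best_orf(imp_by_gene[[g]], genome, min_aa)
    rc <- if (is.null(rb)) "none" else rb$completeness
    ic <- if (is.null(ib)) "none" else ib$completeness
    has_start <- function(cc) cc %in% c("complete", "3prime_partial")
    has_stop <- function(cc) cc %in% c("complete", "5prime_partial")
    new_complete <- rc == "none" && ic == "complete"
    gained_start <- rc %in% c("5prime_partial", "internal") && has_start(ic)
    gained_stop <- rc %in% c("3prime_partial", "internal") && has_stop(ic)
    category <- if (new_complete) "new_complete"
    else if (gained_start && gained_stop) "gained_start+gained_stop"
    else if (gained_start) "gained_start"
    else if (gained_stop) "gained_stop"
    else "unchanged"
    data.frame(gene_id = g, ref_completeness = rc,
               improved_completeness = ic, gained_start = gained_start,
               gained_stop = gained_stop, new_complete = new_complete,
               category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
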
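# Unmapped-read rescue and de novo contig post-processing: poly-A/T
# trimming with length/GC filters, an abundance filter cascade, greedy
# deduplication at a nucleotide identity threshold, coding
# classification, and repeat-novelty calls against a consensus library.

#' Rescue-filter unmapped reads
#'
#' Terminal runs of A (3' end) and T (both ends) longer than 4 nt are
#' trimmed; reads are then retained when longer than 25 nt with GC
#' content above 20\% (both thresholds strict).
#'
#' @param reads named character vector of reads.
#' @return named character vector of retained (trimmed) reads.
#' @export
rescue_filter_reads <- function(reads, min_len = 25L, min_gc = 0.2,
                                max_tail = 4L) {
  if (length(reads) == 0L) return(reads)
  trim_one <- function(s) {
    # 3' A run
    s <- sub(sprintf("A{%d,}$", max_tail + 1L), "", s)
    # T runs at either end
    s <- sub(sprintf("T{%d,}$", max_tail + 1L), "", s)
    s <- sub(sprintf("^T{%d,}", max_tail + 1L), "", s)
    s
  }
  trimmed <- vapply(reads, trim_one, "", USE.NAMES = TRUE)
  keep <- nchar(trimmed) > min_len & .gc_content(trimmed) > min_gc
  trimmed[keep]
}

#' Filter contigs by stage-level TPM
#'
#' @param contigs contig data.frame with a `tpm` column.
#' @param min_tpm contigs with `tpm < min_tpm` are removed.
#' @return the retained rows.
#' @export
filter_contigs_by_tpm <- function(contigs, min_tpm = 10) {
  if (is.null(contigs$tpm) || anyNA(contigs$tpm))
    stop("integrity error: contig TPM not populated")
  contigs[contigs$tpm >= min_tpm, , drop = FALSE]
}

#' Filter contigs by final estimated read count
#'
#' @param contigs contig data.frame with an `estimated_reads` column.
#' @param min_reads contigs with fewer estimated reads are removed.
#' @return the retained rows.
#' @export
filter_contigs_by_reads <- function(contigs, min_reads = 20) {
  if (is.null(contigs$estimated_reads) || anyNA(contigs$estimated_reads))
    stop("integrity error: contig estimated_reads not populated")
  contigs[contigs$estimated_reads >= min_reads, , drop = FALSE]
}

# all k-mers of a sequence and its reverse complement
.seq_kmers <- function(s, k = 11L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  both <- c(s, revcomp(s))
  unique(unlist(lapply(both, function(x)
    substring(x, seq_len(nchar(x) - k + 1L),
              seq_len(nchar(x) - k + 1L) + k - 1L))))
}

.dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# best local alignment of a vs b (optionally both strands of a);
# returns list(matches, aln_width, pattern_span)
.best_local <- function(a, b, both_strands = TRUE, submat = .dna_submat()) {
  cand <- c(a, if (both_strands) revcomp(a))
  best <- NULL
  for (k in seq_along(cand)) {
    aln <- Biostrings::pairwiseAlignment(
      cand[k], b, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      pr <- aln@pattern@range
      best <- list(score = sc, matches = Biostrings::nmatch(aln),
                   aln_width = nchar(as.character(Biostrings::alignedPattern(aln))),
                   pattern_span = IRanges::width(pr),
                   rc = k == 2L)
    }
  }
  best
}

#' Greedy sequence clustering at an identity threshold
#'
#' Contigs are sorted by length descending (ties by id); each contig
#' joins the first existing cluster whose representative aligns with
#' nucleotide identity at least `identity`, where identity is the number
#' of aligned matches divided by the length of the shorter sequence over
#' the best local alignment (both orientations); otherwise it founds a
#' new cluster. The representative of a cluster is its longest (first)
#' member.
#'
#' @param contigs data.frame with `contig_id` and `sequence` columns
#'   (and optionally `estimated_reads`).
#' @param identity identity threshold in `[0,1]`.
#' @details For thresholds of 0.95 and above, candidate pairs are
#'   pre-screened by shared 11-mers (on either strand) before alignment:
#'   an alignment matching 95\% of the shorter sequence must contain an
#'   exact run of at least 11 nt, so the screen cannot drop a qualifying
#'   pair and only saves alignments between unrelated contigs.
#' @return the input data.frame with columns `cluster` (representative
#'   contig id) and `is_representative` appended; row order preserved.
#' @export
greedy_cluster <- function(contigs, identity = 0.95) {
  n <- nrow(contigs)
  cluster <- rep(NA_character_, n)
  if (n == 0L) {
    contigs$cluster <- character(0)
    contigs$is_representative <- logical(0)
    return(contigs)
  }
  lens <- nchar(contigs$sequence)
  ord <- order(-lens, contigs$contig_id)
  submat <- .dna_submat()
  prescreen <- identity >= 0.95
  kmers <- if (prescreen) lapply(contigs$sequence, .seq_kmers, k = 11L)
  reps <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      if (prescreen && !any(kmers[[i]] %in% kmers[[r]])) next
      shorter <- min(lens[i], lens[r])
      b <- .best_local(contigs$sequence[i], contigs$sequence[r],
                       both_strands = TRUE, submat = submat)
      if (b$matches / shorter >= identity) {
        cluster[i] <- contigs$contig_id[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- contigs$contig_id[i]
    }
  }
  contigs$cluster <- cluster
  contigs$is_representative <- contigs$contig_id == cluster
  contigs
}

#' Collapse clusters to their representatives
#'
#' @param clustered output of [greedy_cluster()].
#' @return representative rows only, with `estimated_reads` (when
#'   present) summed over cluster members.
#' @export
collapse_clusters <- function(clustered) {
  reps <- clustered[clustered$is_representative, , drop = FALSE]
  if (!is.null(clustered$estimated_reads)) {
    sums <- tapply(clustered$estimated_reads, clustered$cluster, sum)
    reps$estimated_reads <- as.numeric(sums[reps$contig_id])
  }
  reps
}

#' Classify a contig as coding or non-coding
#'
#' A contig is coding when it carries a six-frame ORF of at least
#' `min_aa` codons, or (when a protein set is supplied) a translated
#' exact 8-mer seed extends along its diagonal to an ungapped alignment
#' covering at least 50 aa at 40\% identity or better.
#'
#' @param sequence contig nucleotide sequence.
#' @param protein_set optional named character vector of amino-acid
#'   sequences.
#' @param min_aa ORF length threshold in codons.
#' @return list with `coding` (logical) and `completeness` (label from
#'   [assign_contig_completeness()], `NA` when non-coding).
#' @export
classify_contig_coding <- function(sequence, protein_set = NULL,
                                   min_aa = 100L) {
  calls <- find_orfs(sequence, min_aa = min_aa, strands = "both")
  coding <- nrow(calls) > 0L
  if (!coding && !is.null(protein_set) && length(protein_set))
    coding <- .protein_seed_match(sequence, protein_set)
  list(coding = coding,
       completeness = if (nrow(calls)) assign_contig_completeness(calls)
       else NA_character_)
}

.translate_frames <- function(sequence) {
  out <- character(0)
  for (s in c(sequence, revcomp(sequence))) {
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < 1L) next
      sub <- substring(s, f + 1L, f + n_cod * 3L)
      out <- c(out, suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X"))))
    }
  }
  out
}

# translated exact 8-mer seed + ungapped diagonal window of >= 50 aa at
# >= 40% identity
.protein_seed_match <- function(sequence, protein_set, seed_len = 8L,
                                min_cov = 50L, min_id = 0.4) {
  peps <- .translate_frames(sequence)
  for (pep in peps) {
    np <- nchar(pep)
    if (np < min_cov) next
    for (prot in protein_set) {
      npr <- nchar(prot)
      if (npr < min_cov) next
      # exact seed positions
      for (i in seq_len(max(np - seed_len + 1L, 0L))) {
        seed <- substring(pep, i, i + seed_len - 1L)
        if (grepl("*", seed, fixed = TRUE)) next
        j <- regexpr(seed, prot, fixed = TRUE)
        if (j < 0L) next
        # diagonal overlap window
        off <- j - i
        a0 <- max(1L, 1L - off)
        a1 <- min(np, npr - off)
        if (a1 - a0 + 1L < min_cov) next
        pa <- strsplit(substring(pep, a0, a1), "")[[1L]]
        pb <- strsplit(substring(prot, a0 + off, a1 + off), "")[[1L]]
        eq <- as.integer(pa == pb)
        cs <- c(0L, cumsum(eq))
        w <- min_cov
        L <- length(eq)
        if (L >= w) {
          ident <- (cs[(w + 1L):(L + 1L)] - cs[1:(L - w + 1L)]) / w
          if (any(ident >= min_id)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Compare a contig against a repeat consensus library
#'
#' The best local alignment against the library decides the call:
#' `known` when identity and contig coverage both clear their
#' thresholds; `novel` when an alignment qualifying as a hit (at least
#' 30 aligned nt at 60\% identity) exists but falls below either
#' threshold; `no_hit` otherwise.
#'
#' @param sequence contig sequence.
#' @param repeat_library named character vector of consensus sequences.
#' @param min_identity,min_coverage thresholds for a `known` call.
#' @return one of `"known"`, `"novel"`, `"no_hit"`.
#' @export
repeat_novelty_call <- function(sequence, repeat_library,
                                min_identity = 0.8, min_coverage = 0.5) {
  if (length(repeat_library) == 0L) {
    warning("empty repeat library; all contigs reported no_hit")
    return("no_hit")
  }
  submat <- .dna_submat()
  best <- NULL
  for (lib in repeat_library) {
    b <- .best_local(sequence, lib, both_strands = TRUE, submat = submat)
    if (is.null(best) || b$score > best$score) best <- b
  }
  identity <- best$matches / max(best$aln_width, 1L)
  coverage <- best$pattern_span / nchar(sequence)
  is_hit <- best$pattern_span >= 30L && identity >= 0.6
  if (is_hit && identity >= min_identity && coverage >= min_coverage)
    "known"
  else if (is_hit) "novel"
  else "no_hit"
}

#' Run the contig filter cascade
#'
#' Fixed order: stage-level TPM filter, within-stage deduplication, the
#' quality gate (an external pass/fail table; pass-through when absent),
#' coding classification, cross-stage deduplication, final
#' estimated-reads filter, and (when a library is given) repeat-novelty
#' calls. Re-running the cascade on its own output is idempotent.
#'
#' @param contigs contig data.frame (`contig_id`, `stage`, `sequence`,
#'   `tpm`, `estimated_reads`).
#' @param protein_set optional protein sequences for homology evidence.
#' @param repeat_library optional repeat consensus sequences.
#' @param quality_scores optional data.frame (`contig_id`, `pass`).
#' @param min_tpm,min_reads,identity,min_aa cascade thresholds.
#' @return data.frame of retained non-redundant contigs with `cluster`,
#'   `coding`, `completeness` and `repeat_call` columns.
#' @export
rescue_pipeline <- function(contigs, protein_set = NULL,
                            repeat_library = NULL, quality_scores = NULL,
                            min_tpm = 10, min_reads = 20,
                            identity = 0.95, min_aa = 100L) {
  kept <- filter_contigs_by_tpm(contigs, min_tpm)
  # within-stage dedup
  by_stage <- split(kept, kept$stage)
  kept <- do.call(rbind, lapply(by_stage, function(s)
    collapse_clusters(greedy_cluster(s, identity))))
  if (!is.null(quality_scores)) {
    fail <- quality_scores$contig_id[!quality_scores$pass]
    kept <- kept[!kept$contig_id %in% fail, , drop = FALSE]
  }
  cls <- lapply(kept$sequence, classify_contig_coding,
                protein_set = protein_set, min_aa = min_aa)
  kept$coding <- vapply(cls, `[[`, TRUE, "coding")
  kept$completeness <- vapply(cls, `[[`, "", "completeness")
  # cross-stage dedup over the merged set
  kept <- collapse_clusters(greedy_cluster(kept, identity))
  kept <- filter_contigs_by_reads(kept, min_reads)
  kept$repeat_call <- if (!is.null(repeat_library))
    vapply(kept$sequence, repeat_novelty_call, "",
           repeat_library = repeat_library) else NA_character_
  rownames(kept) <- NULL
  kept
}
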
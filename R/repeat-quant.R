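# Repeat-class expression: merge overlapping same-class/strand features,
# keep regions longer than 0.5 kb, assign read pairs fractionally by
# multi-mapping multiplicity with pair-level ambiguity exclusion.

#' Merge overlapping repeat features of the same class and strand
#'
#' Features with identical (contig, class, strand) that strictly overlap
#' are merged transitively; adjacent-but-not-overlapping features stay
#' separate, and distinct classes are never merged.
#'
#' @param features repeat feature data.frame from
#'   [read_repeat_annotation()].
#' @return data.frame of merged regions (`region_id`, `contig`, `start`,
#'   `end`, `strand`, `repeat_class`, `members`, `length`), sorted by
#'   contig then start.
#' @export
merge_repeat_features <- function(features) {
  empty <- data.frame(region_id = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), repeat_class = character(0),
                      members = character(0), length = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0L) return(empty)
  key <- paste(features$contig, features$repeat_class, features$strand,
               sep = "\r")
  out <- NULL
  for (k in unique(key)) {
    sub <- features[key == k, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, red)
    mem <- split(sub$feature_id[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov))
    out <- rbind(out, data.frame(
      contig = sub$contig[1L], start = IRanges::start(red) - 1L,
      end = IRanges::end(red), strand = sub$strand[1L],
      repeat_class = sub$repeat_class[1L],
      members = vapply(mem, paste, "", collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  out$region_id <- sprintf("MR%05d", seq_len(nrow(out)))
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out[, c("region_id", "contig", "start", "end", "strand", "repeat_class",
          "members", "length")]
}

#' Keep merged regions longer than a minimum length
#'
#' @param regions merged regions from [merge_repeat_features()].
#' @param min_bp strict lower bound on region length (default 500, i.e.
#'   regions longer than 0.5 kb).
#' @return the retained rows.
#' @export
filter_regions_by_length <- function(regions, min_bp = 500) {
  regions[regions$length > min_bp, , drop = FALSE]
}

# GRanges of merged regions / gene exons for assignment (unstranded)
.regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$contig,
    ranges = IRanges::IRanges(start = regions$start + 1L,
                              end = regions$end),
    strand = "*", region_id = regions$region_id,
    repeat_class = regions$repeat_class)
}

#' Assign read pairs fractionally to repeat classes and genes
#'
#' Each genomic placement of a pair contributes weight `1/n_hits` to the
#' feature(s) it overlaps (one shared base suffices; assignment is
#' unstranded). A pair whose placements, taken together, touch more than
#' one element class (gene vs the individual repeat classes) contributes
#' its full weight to the ambiguous bucket instead. Pairs failing the
#' alignment flags are excluded; placement weight touching no feature is
#' unassigned. Per sample: assigned + ambiguous + excluded + unassigned
#' equals the number of pairs exactly.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param gene_models list of transcript models (the gene annotation),
#'   may be empty.
#' @param regions filtered merged repeat regions.
#' @return list with `class_summary` (per sample and class: assigned
#'   weight and pie fraction), `region_counts` (per region and sample),
#'   and `totals` (per sample: assigned, ambiguous, excluded, unassigned,
#'   pairs).
#' @export
assign_pairs_fractional <- function(alignments, gene_models, regions) {
  reg_gr <- .regions_granges(regions)
  gene_gr <- models_exon_granges(gene_models)
  known <- unique(c(as.character(GenomicRanges::seqnames(reg_gr)),
                    as.character(GenomicRanges::seqnames(gene_gr))))
  samples <- unique(alignments$sample)
  class_rows <- NULL
  region_rows <- list()
  totals <- NULL
  for (s in samples) {
    sub <- alignments[alignments$sample == s, , drop = FALSE]
    pair_flags <- tapply(sub$both_ends_aligned & sub$same_contig_strand,
                         sub$pair_id, all)
    n_pairs <- length(pair_flags)
    excluded_ids <- names(pair_flags)[!pair_flags]
    ok <- sub[!sub$pair_id %in% excluded_ids, , drop = FALSE]
    # expand placements to blocks
    blocks <- parse_blocks(ok$blocks)
    nb <- vapply(blocks, nrow, 0L)
    if (sum(nb) > 0L) {
      bgr <- GenomicRanges::GRanges(
        seqnames = rep(ok$contig, nb),
        ranges = IRanges::IRanges(
          start = unlist(lapply(blocks, function(b) b[, 1L])) + 1L,
          end = unlist(lapply(blocks, function(b) b[, 2L]))),
        strand = "*")
      row_of <- rep(seq_len(nrow(ok)), nb)
      # per placement: which repeat regions / genes do its blocks touch
      rhits <- suppressWarnings(GenomicRanges::findOverlaps(
        bgr, reg_gr, ignore.strand = TRUE))
      ghits <- if (length(gene_gr))
        suppressWarnings(GenomicRanges::findOverlaps(bgr, gene_gr,
                                                     ignore.strand = TRUE))
      else NULL
      pl_regions <- lapply(seq_len(nrow(ok)), function(i) integer(0))
      for (k in seq_along(rhits)) {
        i <- row_of[S4Vectors::queryHits(rhits)[k]]
        pl_regions[[i]] <- union(pl_regions[[i]],
                                 S4Vectors::subjectHits(rhits)[k])
      }
      pl_gene <- rep(FALSE, nrow(ok))
      if (!is.null(ghits) && length(ghits))
        pl_gene[unique(row_of[S4Vectors::queryHits(ghits)])] <- TRUE
    } else {
      pl_regions <- list()
      pl_gene <- logical(0)
    }
    # pair-level class sets
    assigned_w <- setNames(rep(0, nrow(regions)), regions$region_id)
    class_w <- setNames(rep(0, length(unique(regions$repeat_class))),
                        unique(regions$repeat_class))
    gene_w <- 0; ambiguous_w <- 0; unassigned_w <- 0
    for (pid in split(seq_len(nrow(ok)), ok$pair_id)) {
      classes <- character(0)
      if (any(pl_gene[pid])) classes <- "gene"
      reg_ix <- unique(unlist(pl_regions[pid]))
      if (length(reg_ix))
        classes <- c(classes, unique(regions$repeat_class[reg_ix]))
      if (length(classes) > 1L) {
        ambiguous_w <- ambiguous_w + 1
        next
      }
      n_hits <- ok$n_hits[pid[1L]]
      w <- 1 / n_hits
      if (length(pid) < n_hits)  # placements absent from the table
        unassigned_w <- unassigned_w + (n_hits - length(pid)) * w
      for (i in pid) {
        ri <- pl_regions[[i]]
        if (length(ri)) {
          share <- w / length(ri)
          assigned_w[ri] <- assigned_w[ri] + share
          class_w[regions$repeat_class[ri[1L]]] <-
            class_w[regions$repeat_class[ri[1L]]] + w
        } else if (pl_gene[i]) {
          gene_w <- gene_w + w
        } else {
          unassigned_w <- unassigned_w + w
        }
      }
    }
    tot_assigned <- sum(class_w) + gene_w
    totals <- rbind(totals, data.frame(
      sample = s, pairs = n_pairs, assigned = tot_assigned,
      gene_assigned = gene_w, repeat_assigned = sum(class_w),
      ambiguous = ambiguous_w, excluded = length(excluded_ids),
      unassigned = unassigned_w, stringsAsFactors = FALSE))
    if (length(class_w))
      class_rows <- rbind(class_rows, data.frame(
        sample = s, repeat_class = names(class_w),
        assigned_weight = unname(class_w),
        pie_fraction = if (sum(class_w) > 0)
          unname(class_w) / sum(class_w) else 0,
        stringsAsFactors = FALSE))
    region_rows[[s]] <- data.frame(
      sample = s, region_id = regions$region_id,
      repeat_class = regions$repeat_class,
      weight = unname(assigned_w), stringsAsFactors = FALSE)
  }
  rownames(totals) <- NULL
  region_counts <- if (length(region_rows))
    do.call(rbind, c(region_rows, list(make.row.names = FALSE))) else NULL
  list(class_summary = class_rows, region_counts = region_counts,
       totals = totals)
}
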
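# Classification of transfrags against a reference annotation using
# intron-chain class codes, acceptance of novel isoforms/genes under the
# support, isoform-fraction and CPM filters, and strand-aware measurement
# of 5'/3' gene extensions.

#' Build an overlap index over reference transcript models
#'
#' @param models list of reference `transcript_model`.
#' @return an opaque index used by [classify_transfrags()].
#' @export
reference_index <- function(models) {
  gr <- models_exon_granges(models)
  chains <- vapply(models, tx_chain_key, "")
  structure(list(models = models, exons = gr,
                 ids = model_ids(models), genes = model_genes(models),
                 chains = chains),
            class = "reference_index")
}

#' Classify one transfrag against the reference
#'
#' Class codes: `"="` for an identical ordered intron chain with a
#' same-strand reference transcript (terminal-exon boundary changes do
#' not break the match), `"j"` for a multi-exon transfrag sharing at
#' least one junction (but not the full chain) with a same-strand
#' reference transcript, `"u"` for no exonic overlap with any reference
#' transcript on either strand, and `"other"` for all remaining overlap
#' patterns (including transfrags spanning two same-strand reference
#' genes), which are excluded downstream.
#'
#' @param tf a [transfrag()] (or bare `transcript_model`).
#' @param index a [reference_index()].
#' @return one-row data.frame: `transfrag_id`, `code`,
#'   `matched_reference_transcript`, `matched_locus`.
#' @export
classify_transfrag <- function(tf, index) {
  m <- if (inherits(tf, "transfrag")) tf$model else tf
  ex <- m$exons
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
    stop("integrity error: transfrag '", m$transcript_id,
         "' has unsorted exons")
  qgr <- GenomicRanges::GRanges(
    seqnames = m$contig,
    ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
    strand = "*")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qgr, index$exons,
                                      ignore.strand = TRUE))
  ov_tx <- unique(index$exons$transcript_id[S4Vectors::subjectHits(hits)])
  none <- data.frame(transfrag_id = m$transcript_id, code = "u",
                     matched_reference_transcript = NA_character_,
                     matched_locus = NA_character_, stringsAsFactors = FALSE)
  if (length(ov_tx) == 0L) return(none)
  ov_ix <- match(ov_tx, index$ids)
  same <- ov_ix[vapply(index$models[ov_ix], function(r)
    r$strand == m$strand, TRUE)]
  call <- function(code, tx) data.frame(
    transfrag_id = m$transcript_id, code = code,
    matched_reference_transcript = tx,
    matched_locus = if (is.na(tx)) NA_character_ else
      index$genes[match(tx, index$ids)],
    stringsAsFactors = FALSE)
  if (length(same)) {
    chain <- tx_chain_key(m)
    eq <- same[index$chains[same] == chain]
    if (length(eq)) {
      eq <- eq[order(index$ids[eq])]
      return(call("=", index$ids[eq[1L]]))
    }
    if (length(unique(index$genes[same])) > 1L)
      return(call("other", NA_character_))
    if (nrow(ex) > 1L) {
      jq <- tx_junction_keys(m)
      shared <- vapply(index$models[same], function(r)
        length(intersect(jq, tx_junction_keys(r))), 0L)
      if (any(shared > 0L)) {
        best <- same[order(-shared, index$ids[same])][1L]
        return(call("j", index$ids[best]))
      }
    }
  }
  call("other", NA_character_)
}

#' Classify a list of transfrags
#'
#' @param transfrags list of [transfrag()] records.
#' @param index a [reference_index()].
#' @return data.frame of class-code calls, one row per transfrag, with a
#'   `support_pairs` column appended.
#' @export
classify_transfrags <- function(transfrags, index) {
  rows <- lapply(transfrags, classify_transfrag, index = index)
  out <- do.call(rbind, rows)
  out$support_pairs <- vapply(transfrags, function(t)
    if (inherits(t, "transfrag")) as.numeric(t$support_pairs) else
      NA_real_, 0)
  rownames(out) <- NULL
  out
}

#' Accept novel isoforms among class-"j" transfrags
#'
#' Retains code-"j" transfrags with at least `min_support` supporting
#' read pairs, abundance at least `min_isoform_fraction` of the gene's
#' major-isoform abundance (compared in the condition where the
#' candidate's abundance is maximal), and CPM above `min_cpm` in at least
#' one condition. The major-isoform abundance of a gene is the maximum
#' per-condition abundance over all transfrags matched to it (codes "="
#' and "j"); ties for the major isoform are resolved by transcript-id
#' order, which does not affect the maximum.
#'
#' @param calls class-code calls from [classify_transfrags()].
#' @param transfrags the classified transfrag list.
#' @param cpm_table matrix of per-transfrag CPM, rows named by transfrag
#'   id, one column per condition.
#' @param min_support,min_isoform_fraction,min_cpm acceptance thresholds.
#' @return character vector of accepted transfrag ids.
#' @export
accept_novel_isoforms <- function(calls, transfrags, cpm_table,
                                  min_support = 20,
                                  min_isoform_fraction = 0.4,
                                  min_cpm = 1) {
  tf_ids <- vapply(transfrags, function(t) t$model$transcript_id, "")
  if (!all(calls$transfrag_id %in% tf_ids))
    stop("integrity error: call references unknown transfrag")
  names(transfrags) <- tf_ids
  # per-gene, per-condition major isoform abundance over matched transfrags
  matched <- calls[calls$code %in% c("=", "j"), , drop = FALSE]
  gene_of <- setNames(matched$matched_locus, matched$transfrag_id)
  major <- list()
  for (id in matched$transfrag_id) {
    g <- gene_of[[id]]
    ab <- transfrags[[id]]$abundance
    major[[g]] <- if (is.null(major[[g]])) ab else pmax(major[[g]], ab)
  }
  accepted <- character(0)
  jcalls <- calls[calls$code == "j", , drop = FALSE]
  for (i in seq_len(nrow(jcalls))) {
    id <- jcalls$transfrag_id[i]
    tf <- transfrags[[id]]
    if (tf$support_pairs < min_support) next
    g <- jcalls$matched_locus[i]
    ab <- tf$abundance
    cond <- names(ab)[which.max(ab)]
    if (ab[[cond]] < min_isoform_fraction * major[[g]][[cond]]) next
    cpm <- cpm_table[id, , drop = TRUE]
    if (!any(cpm > min_cpm)) next
    accepted <- c(accepted, id)
  }
  accepted
}

#' Cluster class-"u" transfrags into novel gene loci
#'
#' Code-"u" transfrags with sufficient support are clustered by
#' same-strand exonic overlap (transitive closure); each cluster becomes
#' one novel locus with its members as isoforms. Single-exon transfrags
#' are eligible.
#'
#' @param calls class-code calls.
#' @param transfrags the classified transfrag list.
#' @param min_support minimum supporting read pairs.
#' @return data.frame with columns `locus_id` (`XLOC_`-style, ordered by
#'   contig and start), `transfrag_id`, `contig`, `strand`, `start`,
#'   `end` (locus span).
#' @export
call_novel_genes <- function(calls, transfrags, min_support = 20) {
  tf_ids <- vapply(transfrags, function(t) t$model$transcript_id, "")
  names(transfrags) <- tf_ids
  sel <- calls$transfrag_id[calls$code == "u" &
                              calls$support_pairs >= min_support]
  empty <- data.frame(locus_id = character(0), transfrag_id = character(0),
                      contig = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(sel) == 0L) return(empty)
  models <- lapply(transfrags[sel], `[[`, "model")
  gr <- models_exon_granges(models)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  qi <- match(gr$transcript_id[S4Vectors::queryHits(hits)], sel)
  si <- match(gr$transcript_id[S4Vectors::subjectHits(hits)], sel)
  # union-find over transfrags
  parent <- seq_along(sel)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_along(qi)) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_along(sel), find, 0L)
  spans <- t(vapply(models, tx_span, numeric(2)))
  groups <- split(seq_along(sel), comp)
  locus <- do.call(rbind, lapply(groups, function(ix) data.frame(
    contig = models[[ix[1L]]]$contig, strand = models[[ix[1L]]]$strand,
    start = min(spans[ix, 1L]), end = max(spans[ix, 2L]),
    members = I(list(sel[ix])), stringsAsFactors = FALSE)))
  ord <- order(locus$contig, locus$start)
  locus <- locus[ord, , drop = FALSE]
  rows <- lapply(seq_len(nrow(locus)), function(i) {
    mem <- locus$members[[i]]
    data.frame(locus_id = sprintf("XLOC_%06d", i), transfrag_id = mem,
               contig = locus$contig[i], strand = locus$strand[i],
               start = locus$start[i], end = locus$end[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count genes expressed above a read-pair cutoff
#'
#' @param count_table gene-level count matrix (genes x samples).
#' @param meta sample metadata with `sample` and `condition` columns.
#' @param threshold minimum summed replicate pairs per condition
#'   (default 40; 10 reproduces the customary permissive cutoff).
#' @return named list, per condition, of expressed gene-id vectors.
#' @export
count_expressed_genes <- function(count_table, meta, threshold = 40) {
  if (any(count_table < 0)) stop("integrity error: negative counts")
  conds <- unique(meta$condition)
  out <- lapply(conds, function(cn) {
    cols <- meta$sample[meta$condition == cn]
    tot <- rowSums(count_table[, cols, drop = FALSE])
    rownames(count_table)[tot >= threshold]
  })
  setNames(out, conds)
}

#' Build the improved annotation from classification results
#'
#' Reference transcripts whose intron chain was matched by an "="
#' transfrag (with sufficient support) take that transfrag's exon
#' boundaries; accepted "j" transfrags are added as new isoforms of their
#' matched gene; all remaining reference transcripts are kept unchanged.
#'
#' @param reference list of reference models.
#' @param transfrags classified transfrag list.
#' @param calls class-code calls.
#' @param accepted_isoforms ids from [accept_novel_isoforms()].
#' @param min_support minimum support for a boundary update.
#' @return list of transcript models (the improved annotation).
#' @export
build_improved_annotation <- function(reference, transfrags, calls,
                                      accepted_isoforms = character(0),
                                      min_support = 20) {
  tf_ids <- vapply(transfrags, function(t) t$model$transcript_id, "")
  names(transfrags) <- tf_ids
  upd <- calls[calls$code == "=" & calls$support_pairs >= min_support, ,
               drop = FALSE]
  update_for <- setNames(upd$transfrag_id,
                         upd$matched_reference_transcript)
  improved <- lapply(reference, function(r) {
    tfid <- update_for[r$transcript_id]
    if (is.na(tfid)) return(r)
    tm <- transfrags[[tfid]]$model
    transcript_model(r$transcript_id, r$gene_id, r$contig, r$strand,
                     tm$exons, cds = r$cds, attributes = r$attributes)
  })
  jcalls <- calls[calls$transfrag_id %in% accepted_isoforms, , drop = FALSE]
  iso <- lapply(seq_len(nrow(jcalls)), function(i) {
    tm <- transfrags[[jcalls$transfrag_id[i]]]$model
    gid <- jcalls$matched_locus[i]
    transcript_model(paste0(gid, ".", tm$transcript_id), gid, tm$contig,
                     tm$strand, tm$exons)
  })
  c(improved, iso)
}

#' Measure 5'/3' gene extensions of an improved annotation
#'
#' Extensions are measured on genomic termini of the gene span (union
#' over isoforms), strand-aware: the 5' extension is the
#' transcription-direction distance from the reference gene's 5'-most
#' terminus to the improved gene's 5'-most terminus, floored at zero.
#' Genes absent from the reference are skipped with a notice.
#'
#' @param improved,reference lists of transcript models sharing gene ids.
#' @return data.frame with `gene_id`, `five_prime_ext_bp`,
#'   `three_prime_ext_bp` and `category` (`"5' only"`, `"3' only"`,
#'   `"both"`, `"none"`).
#' @export
measure_extensions <- function(improved, reference) {
  imp <- gene_spans(improved)
  ref <- gene_spans(reference)
  missing <- setdiff(imp$gene_id, ref$gene_id)
  if (length(missing))
    message("measure_extensions: skipping ", length(missing),
            " gene(s) absent from the reference")
  shared <- intersect(imp$gene_id, ref$gene_id)
  ii <- match(shared, imp$gene_id)
  ri <- match(shared, ref$gene_id)
  plus <- ref$strand[ri] != "-"
  five <- ifelse(plus, ref$start[ri] - imp$start[ii],
                 imp$end[ii] - ref$end[ri])
  three <- ifelse(plus, imp$end[ii] - ref$end[ri],
                  ref$start[ri] - imp$start[ii])
  five <- pmax(five, 0)
  three <- pmax(three, 0)
  category <- ifelse(five > 0 & three > 0, "both",
                     ifelse(five > 0, "5' only",
                            ifelse(three > 0, "3' only", "none")))
  data.frame(gene_id = shared, five_prime_ext_bp = five,
             three_prime_ext_bp = three, category = category,
             stringsAsFactors = FALSE)
}
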
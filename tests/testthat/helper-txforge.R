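# shared fixture builders (all fixtures are generated in code)

mk_tx <- function(id, gene, exons, strand = "+", contig = "chr1",
                  cds = NULL, attributes = character()) {
  transcript_model(id, gene, contig, strand,
                   do.call(rbind, exons), cds = if (!is.null(cds))
                     do.call(rbind, cds), attributes = attributes)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random multi-exon transcript model on a given contig/strand
rand_model <- function(id, gene = paste0("g_", id), contig = "chr1",
                       strand = sample(c("+", "-"), 1L),
                       n_exons = sample(1:5, 1L), origin = NULL) {
  if (is.null(origin)) origin <- sample(1:100000, 1L)
  lens <- sample(50:400, n_exons, replace = TRUE)
  gaps <- if (n_exons > 1L) sample(60:500, n_exons - 1L, replace = TRUE)
  else integer(0)
  starts <- origin + cumsum(c(0L, head(lens, -1L) + gaps))
  transcript_model(id, gene, contig, strand, cbind(starts, starts + lens))
}

# exhaustive junction-set classification oracle, written independently of
# the package's interval-indexed implementation
oracle_classify <- function(tf_model, ref_models) {
  junc <- function(m) {
    ex <- m$exons
    if (nrow(ex) < 2L) return(character(0))
    paste0(ex[-nrow(ex), 2L], "_", ex[-1L, 1L])
  }
  exonic_overlap <- function(a, b) {
    if (a$contig != b$contig) return(FALSE)
    for (i in seq_len(nrow(a$exons)))
      for (j in seq_len(nrow(b$exons)))
        if (a$exons[i, 1L] < b$exons[j, 2L] &&
            b$exons[j, 1L] < a$exons[i, 2L]) return(TRUE)
    FALSE
  }
  ov <- Filter(function(r) exonic_overlap(tf_model, r), ref_models)
  if (length(ov) == 0L) return("u")
  same <- Filter(function(r) r$strand == tf_model$strand, ov)
  jt <- junc(tf_model)
  for (r in same)
    if (identical(jt, junc(r))) return("=")
  if (length(unique(vapply(same, `[[`, "", "gene_id"))) > 1L)
    return("other")
  if (nrow(tf_model$exons) > 1L)
    for (r in same)
      if (length(intersect(jt, junc(r))) > 0L) return("j")
  "other"
}

# brute-force ORF oracle: enumerate every in-frame ATG/stop combination
oracle_orfs <- function(seq, min_aa, strands = "forward") {
  scan1 <- function(s, strand) {
    out <- NULL
    L <- nchar(s)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 1L) next
      at <- f + 3L * (seq_len(n_cod) - 1L) + 1L
      cod <- substring(s, at, at + 2L)
      stops <- which(cod %in% c("TAA", "TAG", "TGA"))
      atgs <- which(cod == "ATG")
      # complete: first ATG of each stop-delimited segment
      for (st in stops) {
        prev <- stops[stops < st]
        lo <- if (length(prev)) max(prev) + 1L else 1L
        a <- atgs[atgs >= lo & atgs < st]
        if (length(a)) {
          aa <- st - min(a)
          if (aa >= min_aa)
            out <- rbind(out, data.frame(
              frame = f, strand = strand,
              start = f + (min(a) - 1L) * 3L, end = f + st * 3L,
              aa_length = aa, completeness = "complete"))
        } else if (lo == 1L && st - 1L >= min_aa) {
          out <- rbind(out, data.frame(
            frame = f, strand = strand, start = f, end = f + st * 3L,
            aa_length = st - 1L, completeness = "5prime_partial"))
        }
      }
      # tail segment
      lo <- if (length(stops)) max(stops) + 1L else 1L
      a <- atgs[atgs >= lo]
      if (length(a)) {
        aa <- n_cod - min(a) + 1L
        if (aa >= min_aa)
          out <- rbind(out, data.frame(
            frame = f, strand = strand,
            start = f + (min(a) - 1L) * 3L, end = f + n_cod * 3L,
            aa_length = aa, completeness = "3prime_partial"))
      } else if (lo == 1L && length(stops) == 0L && n_cod >= min_aa) {
        out <- rbind(out, data.frame(
          frame = f, strand = strand, start = f, end = f + n_cod * 3L,
          aa_length = n_cod, completeness = "internal"))
      }
    }
    out
  }
  out <- scan1(seq, "+")
  if (strands == "both") out <- rbind(out, scan1(revcomp(seq), "-"))
  if (is.null(out)) return(txforge:::.empty_orf_df())
  rownames(out) <- NULL
  out
}

mk_transfrag <- function(model, support = 25L,
                         abundance = c(PVS = 50, Egg = 50)) {
  transfrag(model, support, abundance)
}
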
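# GTF2.2 reading/writing. External text is 1-based inclusive; internal
# models are 0-based half-open. Conversion happens here and only here.

.parse_gtf_attributes <- function(attr, lineno) {
  # key "value"; pairs, trailing ';' optional
  out <- character(0)
  rest <- trimws(attr)
  pat <- '^([A-Za-z_][A-Za-z0-9_]*)\\s+"([^"]*)"\\s*;?\\s*'
  while (nzchar(rest)) {
    mm <- regmatches(rest, regexec(pat, rest))[[1L]]
    if (length(mm) == 0L)
      stop("parse error at line ", lineno,
           ": malformed attribute field: ", attr)
    out[mm[2L]] <- mm[3L]
    rest <- substring(rest, nchar(mm[1L]) + 1L)
  }
  out
}

#' Read a GTF stream into transcript models
#'
#' Parses `exon` and `CDS` features carrying `gene_id` and `transcript_id`
#' attributes into one [transcript_model()] per transcript. 1-based
#' inclusive GTF coordinates are converted to the internal 0-based
#' half-open convention and exon order is normalized.
#'
#' @param x a file path, or a character vector of GTF lines.
#' @return a list of `transcript_model` objects, in order of first
#'   appearance of each transcript.
#' @export
read_gtf <- function(x) {
  lines <- .as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  linenos <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("parse error at line ", linenos[bad[1L]],
         ": expected 9 tab-separated fields")
  tab <- do.call(rbind, fields)
  feat <- tab[, 3L]
  sel <- feat %in% c("exon", "CDS")
  tab <- tab[sel, , drop = FALSE]
  linenos <- linenos[sel]
  if (nrow(tab) == 0L) return(list())
  attrs <- lapply(seq_len(nrow(tab)),
                  function(i) .parse_gtf_attributes(tab[i, 9L], linenos[i]))
  tid <- vapply(attrs, function(a) unname(a["transcript_id"]), "")
  gid <- vapply(attrs, function(a) unname(a["gene_id"]), "")
  if (anyNA(tid) || anyNA(gid))
    stop("parse error at line ", linenos[which(is.na(tid) | is.na(gid))[1L]],
         ": missing gene_id/transcript_id attribute")
  start <- suppressWarnings(as.numeric(tab[, 4L]))
  end <- suppressWarnings(as.numeric(tab[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop("parse error at line ", linenos[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric coordinates")
  models <- vector("list", 0L)
  for (id in unique(tid)) {
    ix <- which(tid == id)
    if (length(unique(tab[ix, 1L])) != 1L)
      stop("integrity error: transcript '", id, "' has exons on mixed contigs")
    if (length(unique(tab[ix, 7L])) != 1L)
      stop("integrity error: transcript '", id, "' has exons on mixed strands")
    is_exon <- tab[ix, 3L] == "exon"
    exi <- ix[is_exon]
    cdi <- ix[!is_exon]
    if (length(exi) == 0L)
      stop("integrity error: transcript '", id, "' has CDS but no exons")
    extra <- attrs[[exi[1L]]]
    extra <- extra[setdiff(names(extra), c("gene_id", "transcript_id"))]
    models[[length(models) + 1L]] <- transcript_model(
      transcript_id = id,
      gene_id = gid[exi[1L]],
      contig = tab[exi[1L], 1L],
      strand = tab[exi[1L], 7L],
      exons = cbind(start[exi] - 1, end[exi]),
      cds = if (length(cdi)) cbind(start[cdi] - 1, end[cdi]) else NULL,
      attributes = extra)
  }
  models
}

#' Write transcript models as GTF text
#'
#' Exons (and CDS segments) are emitted in genome order with coordinates
#' converted back to 1-based inclusive. Transcript-level attributes are
#' repeated on every line of the transcript.
#'
#' @param models list of `transcript_model`.
#' @param file optional path; when `NULL` the lines are returned.
#' @param source source column value.
#' @return character vector of GTF lines (invisibly when `file` is given).
#' @export
write_gtf <- function(models, file = NULL, source = "txforge") {
  for (m in models) validate_transcript_model(m)
  lines <- c("#gtf produced by txforge")
  for (m in models) {
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                         m$gene_id, m$transcript_id)
    if (length(m$attributes))
      base_attr <- paste(base_attr, paste0(
        names(m$attributes), ' "', m$attributes, '";', collapse = " "))
    emit <- function(feat, iv) {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$contig, source, feat, as.integer(iv[, 1L] + 1),
              as.integer(iv[, 2L]), m$strand,
              base_attr)
    }
    lines <- c(lines, emit("exon", m$exons))
    if (!is.null(m$cds) && nrow(m$cds) > 0L)
      lines <- c(lines, emit("CDS", m$cds))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x)
  else if (length(x) == 1L && grepl("\n", x)) strsplit(x, "\n")[[1L]]
  else x
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
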
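# RepeatMasker-style repeat annotation, as a GFF3 dialect whose attribute
# column carries class= and family= keys.

#' Read a repeat annotation (GFF3 dialect)
#'
#' Each line becomes one repeat feature. Coordinates are converted from
#' 1-based inclusive to the internal 0-based half-open convention. The
#' attribute column must carry a `class=` key; `family=` and `ID=` are
#' optional.
#'
#' @param x file path or character vector of GFF3 lines.
#' @return data.frame with columns `feature_id`, `contig`, `start`, `end`,
#'   `strand`, `repeat_class`, `family`, in input order.
#' @export
read_repeat_annotation <- function(x) {
  lines <- .as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  linenos <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(feature_id = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), repeat_class = character(0),
                      family = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("parse error at line ", linenos[bad[1L]],
         ": expected 9 tab-separated fields")
  tab <- do.call(rbind, fields)
  attr_one <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)\\s*", key, "=([^;]*)"), a))[[1L]]
    if (length(m) == 0L) NA_character_ else m[3L]
  }
  cls <- vapply(tab[, 9L], attr_one, "", key = "class", USE.NAMES = FALSE)
  if (anyNA(cls) || any(!nzchar(cls)))
    stop("parse error at line ",
         linenos[which(is.na(cls) | !nzchar(cls))[1L]],
         ": missing class attribute")
  fam <- vapply(tab[, 9L], attr_one, "", key = "family", USE.NAMES = FALSE)
  fid <- vapply(tab[, 9L], attr_one, "", key = "ID", USE.NAMES = FALSE)
  fid[is.na(fid)] <- paste0("rep_", which(is.na(fid)))
  start <- as.numeric(tab[, 4L]) - 1
  end <- as.numeric(tab[, 5L])
  if (any(end <= start))
    stop("integrity error: repeat feature with non-positive length at line ",
         linenos[which(end <= start)[1L]])
  data.frame(feature_id = fid, contig = tab[, 1L], start = start, end = end,
             strand = tab[, 7L], repeat_class = cls,
             family = ifelse(is.na(fam), "", fam), stringsAsFactors = FALSE)
}

#' Write repeat features (or merged regions) as GFF3
#'
#' @param feats data.frame with `feature_id`, `contig`, `start`, `end`,
#'   `strand`, `repeat_class`, and optionally `family` columns
#'   (internal 0-based half-open coordinates).
#' @param file optional output path.
#' @param type GFF3 type column.
#' @return character vector of GFF3 lines (invisibly when written).
#' @export
write_repeat_gff3 <- function(feats, file = NULL, type = "repeat_region") {
  fam <- if ("family" %in% names(feats)) feats$family else ""
  lines <- c("##gff-version 3",
             sprintf("%s\ttxforge\t%s\t%d\t%d\t.\t%s\t.\tID=%s;class=%s;family=%s",
                     feats$contig, type, as.integer(feats$start + 1),
                     as.integer(feats$end), feats$strand, feats$feature_id,
                     feats$repeat_class, fam))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
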
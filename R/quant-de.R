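# Gene-level pair counting, CPM/TPM, TMM normalization, a
# negative-binomial Wald test for two-group differential expression,
# DEG classification, top-k tables and hypergeometric enrichment.

#' Count read pairs per gene
#'
#' Pairs failing the alignment flags (both ends aligned; mates on one
#' contig and strand) are excluded. Under `unique_only` (the default)
#' only pairs with a single genomic placement are counted. A pair
#' overlapping several genes is assigned to the gene with the largest
#' overlapped base count; ties are counted once for every tied gene
#' (`tie_policy = "all"`), or dropped under `tie_policy = "strict"`.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param annotation list of transcript models.
#' @param multi_policy `"unique_only"` or `"fractional"` (weight
#'   `1/n_hits` per placement).
#' @param tie_policy `"all"` or `"strict"`.
#' @return list with `counts` (genes x samples matrix), `meta`
#'   (inferred sample table), `stats` (per sample: total, excluded,
#'   multi_excluded, assigned, unassigned pairs).
#' @export
count_gene_pairs <- function(alignments, annotation,
                             multi_policy = c("unique_only", "fractional"),
                             tie_policy = c("all", "strict")) {
  multi_policy <- match.arg(multi_policy)
  tie_policy <- match.arg(tie_policy)
  gene_gr <- models_exon_granges(annotation)
  genes <- sort(unique(model_genes(annotation)))
  samples <- sort(unique(alignments$sample))
  counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  stats <- NULL
  known <- unique(vapply(annotation, `[[`, "", "contig"))
  if (nrow(alignments) && !any(alignments$contig %in% known) &&
      length(annotation))
    stop("integrity error: alignment contigs do not match the annotation")
  for (s in samples) {
    sub <- alignments[alignments$sample == s, , drop = FALSE]
    flags <- tapply(sub$both_ends_aligned & sub$same_contig_strand,
                    sub$pair_id, all)
    total <- length(flags)
    excluded <- sum(!flags)
    sub <- sub[sub$pair_id %in% names(flags)[flags], , drop = FALSE]
    multi_excluded <- 0L
    if (multi_policy == "unique_only") {
      multi_ids <- unique(sub$pair_id[sub$n_hits > 1L])
      multi_excluded <- length(multi_ids)
      sub <- sub[sub$n_hits == 1L, , drop = FALSE]
    }
    assigned <- 0; unassigned <- 0
    if (nrow(sub)) {
      blocks <- parse_blocks(sub$blocks)
      nb <- vapply(blocks, nrow, 0L)
      bgr <- GenomicRanges::GRanges(
        seqnames = rep(sub$contig, nb),
        ranges = IRanges::IRanges(
          start = unlist(lapply(blocks, function(b) b[, 1L])) + 1L,
          end = unlist(lapply(blocks, function(b) b[, 2L]))),
        strand = "*")
      row_of <- rep(seq_len(nrow(sub)), nb)
      hits <- suppressWarnings(GenomicRanges::findOverlaps(
        bgr, gene_gr, ignore.strand = TRUE))
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        ovw <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(bgr)[qh], IRanges::ranges(gene_gr)[sh]))
        key <- paste(row_of[qh], gene_gr$gene_id[sh], sep = "\r")
        ov_by <- tapply(ovw, key, sum)
        prow <- as.integer(sub("\r.*", "", names(ov_by)))
        pgene <- sub("^[0-9]+\r", "", names(ov_by))
      } else {
        prow <- integer(0); pgene <- character(0); ov_by <- numeric(0)
      }
      for (pid in split(seq_len(nrow(sub)), sub$pair_id)) {
        w_pl <- 1 / sub$n_hits[pid[1L]]
        got <- FALSE
        for (i in pid) {
          sel <- which(prow == i)
          if (length(sel) == 0L) next
          ov <- as.numeric(ov_by[sel])
          gmax <- pgene[sel][ov == max(ov)]
          if (length(gmax) > 1L && tie_policy == "strict") next
          wgt <- if (multi_policy == "unique_only") 1 else w_pl
          counts[gmax, s] <- counts[gmax, s] + wgt
          got <- TRUE
        }
        if (got) assigned <- assigned + 1 else unassigned <- unassigned + 1
      }
    }
    stats <- rbind(stats, data.frame(
      sample = s, total = total, excluded = excluded,
      multi_excluded = multi_excluded, assigned = assigned,
      unassigned = unassigned, stringsAsFactors = FALSE))
  }
  rownames(stats) <- NULL
  cond <- sub("_[0-9]+$", "", samples)
  meta <- data.frame(sample = samples, condition = cond,
                     replicate = as.integer(sub("^.*_", "", samples)),
                     stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, stats = stats)
}

#' Counts per million and transcripts per million
#'
#' `CPM = count / library_size * 1e6`;
#' `TPM = (count/length) / sum(count/length) * 1e6` per sample.
#'
#' @param counts genes x samples matrix.
#' @param lengths named vector of feature lengths in bp (for TPM).
#' @param library_size optional per-sample totals; defaults to column
#'   sums of `counts` (total assigned pairs).
#' @return list with `cpm` and (when lengths are given) `tpm` matrices.
#' @export
cpm_tpm <- function(counts, lengths = NULL, library_size = NULL) {
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0))
    stop("computation error: zero library size")
  cpm <- sweep(counts, 2L, library_size, "/") * 1e6
  tpm <- NULL
  if (!is.null(lengths)) {
    len <- lengths[rownames(counts)]
    if (anyNA(len)) stop("integrity error: missing feature length")
    rate <- sweep(counts, 1L, len, "/")
    tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  }
  list(cpm = cpm, tpm = tpm)
}

#' Filter genes by minimum CPM in a minimum number of samples
#'
#' @param cpm genes x samples CPM matrix.
#' @param min_cpm strict lower CPM bound.
#' @param min_samples number of samples that must clear it.
#' @return character vector of retained gene ids.
#' @export
filter_low_expression <- function(cpm, min_cpm = 1, min_samples = 2) {
  keep <- rowSums(cpm > min_cpm) >= min_samples
  rownames(cpm)[keep]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against the reference
#' sample (the one whose upper-quartile CPM is closest to the mean upper
#' quartile), per-gene log2 ratios (M) and log2 abundances (A) are
#' computed on library-size-scaled counts, genes with a zero count in
#' either sample are excluded, the top and bottom `trim_m` of genes by M
#' and `trim_a` by A are trimmed, and the factor is 2 to the
#' precision-weighted (inverse binomial variance) mean of the remaining
#' M values. Factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples matrix.
#' @param trim_m,trim_a trim fractions for M and A (defaults 0.30, 0.05).
#' @return named numeric vector of scaling factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("computation error: sample with all zeros")
  uq <- apply(counts, 2L, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0L) return(1)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) f <- 0
  2 ^ f
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene, an NB model with mean `mu_ij = s_j q_i 2^(x_j beta)`
#' (`s_j` = library size times normalization factor, `x_j` the group
#' indicator, Egg vs PVS) is fitted by iteratively reweighted least
#' squares with a gene-wise method-of-moments dispersion (floored at
#' 1e-8) estimated from group-centred normalized counts. Because the
#' gene-wise moment estimate has very few degrees of freedom at two
#' replicates per group, the estimates are pooled through a
#' mean-dispersion trend (a lowess fit of the gene-wise estimates
#' against log mean expression, "fit-only" sharing) and the fitted
#' trend value is used per gene; per-gene departures from the trend are
#' deliberately not modelled (no empirical-Bayes shrinkage). The Wald
#' p-value is two-sided; `padj` is Benjamini-Hochberg over the tested
#' genes.
#'
#' @param counts genes x samples matrix (filtered genes only).
#' @param meta sample metadata with `sample` and `condition` columns.
#' @param factors TMM factors from [tmm_factors()]; defaults to 1.
#' @param lib_size per-sample library sizes; defaults to column sums of
#'   `counts`. Supply the full-experiment totals when testing a subset
#'   of genes.
#' @param condition_order length-2 character: (reference, contrast);
#'   log2 fold-changes are contrast over reference.
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `p_value`, `padj`.
#' @export
nb_wald_test <- function(counts, meta, factors = NULL, lib_size = NULL,
                         condition_order = c("PVS", "Egg")) {
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (any(table(meta$condition) < 2L))
    stop("design error: fewer than 2 replicates in a group")
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)),
                                            colnames(counts))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  s <- lib_size * factors[colnames(counts)]
  s <- s / exp(mean(log(s)))  # geometric-mean-1 size factors
  x <- as.integer(meta$condition == condition_order[2L])
  z <- sweep(counts, 2L, s, "/")
  # gene-wise method-of-moments dispersion from group-centred normalized
  # counts, pooled through a mean-dispersion trend
  raw <- vapply(seq_len(nrow(counts)), function(i) {
    zi <- z[i, ]
    mu <- ave(zi, x)
    v <- sum((zi - mu) ^ 2) / (length(zi) - 2L)
    m <- mean(zi)
    (v - m) / m ^ 2
  }, 0)
  disp <- .trend_dispersion(raw, rowMeans(z))
  X <- cbind(1, x)
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    fit <- suppressWarnings(
      glm.fit(X, y, family = fam, offset = log(s)))
    beta <- fit$coefficients[2L]
    # Wald SE from the weighted information matrix
    w <- fit$weights
    XtWX <- crossprod(X * w, X)
    se <- sqrt(diag(solve(XtWX)))[2L]
    c(beta = beta, se = se)
  }, c(beta = 0, se = 0)))
  log2fc <- res[, "beta"] / log(2)
  zstat <- res[, "beta"] / res[, "se"]
  p <- 2 * pnorm(-abs(zstat))
  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(z),
             log2fc = log2fc, se = res[, "se"] / log(2),
             p_value = p, padj = p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# lowess mean-dispersion trend over gene-wise moment estimates
# (plain least-squares lowess: robustness iterations would bias the
# skewed estimates downward); floored at 1e-8
.trend_dispersion <- function(raw, base_mean, floor = 1e-8) {
  n <- length(raw)
  if (n < 10L) return(pmax(raw, floor))
  lx <- log(pmax(base_mean, 1e-8))
  lw <- stats::lowess(lx, raw, f = 0.5, iter = 0)
  fitted <- stats::approx(lw$x, lw$y, xout = lx, rule = 2,
                          ties = "ordered")$y
  pmax(fitted, floor)
}

#' Label differentially expressed genes
#'
#' `up` when `padj <= padj_threshold` and the linear fold-change
#' (contrast over reference, `2^log2fc`) is at least `fc_threshold`;
#' `down` when it is at most `1/fc_threshold`; otherwise `ns`. Set
#' `log_scale = TRUE` to apply the threshold to |log2fc| instead.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param fc_threshold linear fold-change threshold (default 2.5).
#' @param padj_threshold adjusted-p threshold (default 0.01).
#' @param log_scale interpret `fc_threshold` on the log2 scale.
#' @return `results` with a `label` column appended.
#' @export
classify_degs <- function(results, fc_threshold = 2.5,
                          padj_threshold = 0.01, log_scale = FALSE) {
  fc <- 2 ^ results$log2fc
  sig <- !is.na(results$padj) & results$padj <= padj_threshold
  if (log_scale) {
    up <- sig & results$log2fc >= fc_threshold
    down <- sig & results$log2fc <= -fc_threshold
  } else {
    up <- sig & fc >= fc_threshold
    down <- sig & fc <= 1 / fc_threshold
  }
  results$label <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Top-k differentially expressed genes by average CPM
#'
#' Among DEGs of one direction, genes are ranked by their mean CPM over
#' that condition's samples after removing an exclusion set (e.g.
#' ribosomal-protein genes); the top `k` are returned.
#'
#' @param results labelled results from [classify_degs()].
#' @param cpm genes x samples CPM matrix.
#' @param meta sample metadata.
#' @param direction `"up"` (ranked by Egg CPM) or `"down"` (by PVS CPM).
#' @param k table size.
#' @param exclude gene ids to drop before ranking.
#' @param condition_order (reference, contrast) conditions.
#' @return data.frame `gene_id`, `mean_cpm`, `log2fc`, `padj`, ranked.
#' @export
top_k_table <- function(results, cpm, meta, direction = c("up", "down"),
                        k = 25, exclude = character(0),
                        condition_order = c("PVS", "Egg")) {
  direction <- match.arg(direction)
  if (k < 1) stop("argument error: k must be >= 1")
  cond <- if (direction == "up") condition_order[2L] else
    condition_order[1L]
  cols <- meta$sample[meta$condition == cond]
  sel <- results[results$label == direction &
                   !results$gene_id %in% exclude, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(gene_id = character(0), mean_cpm = numeric(0),
                      log2fc = numeric(0), padj = numeric(0),
                      stringsAsFactors = FALSE))
  mc <- rowMeans(cpm[sel$gene_id, cols, drop = FALSE])
  ord <- order(-mc, sel$gene_id)
  sel <- sel[ord, , drop = FALSE]
  mc <- mc[ord]
  head(data.frame(gene_id = sel$gene_id, mean_cpm = unname(mc),
                  log2fc = sel$log2fc, padj = sel$padj,
                  stringsAsFactors = FALSE), k)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a selected gene
#' set and each term's gene set against a background, with
#' Benjamini-Hochberg correction over the terms having at least one
#' selected gene.
#'
#' @param selected character vector of selected genes (subset of
#'   `background`).
#' @param background character vector, the statistical domain.
#' @param term_map named list: term id -> character vector of genes.
#' @param fdr BH threshold for the `enriched` flag.
#' @return data.frame per tested term: `term`, `overlap`, `term_size`,
#'   `p_value`, `padj`, `enrichment_ratio`, `enriched`.
#' @export
hypergeom_enrichment <- function(selected, background, term_map,
                                 fdr = 0.05) {
  if (!all(selected %in% background))
    stop("integrity error: selected gene absent from background")
  selected <- unique(selected)
  background <- unique(background)
  N <- length(background); n <- length(selected)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(term_map[[tm]], background)
    K <- length(tg)
    ov <- length(intersect(tg, selected))
    if (ov < 1L) return(NULL)
    p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = ov, term_size = K, p_value = p,
               enrichment_ratio = (ov / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p_value = numeric(0),
                      padj = numeric(0), enrichment_ratio = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  out$padj <- p.adjust(out$p_value, "BH")
  out$enriched <- out$padj <= fdr
  out[order(out$p_value), , drop = FALSE]
}
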
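# Synthetic two-condition (PVS, Egg) x two-replicate experiment with a
# planted, machine-readable ground truth. The generator emits a genome, a
# truth annotation, a deliberately degraded "reference" annotation, NB
# counts with planted fold-changes, transfrags, a repeat landscape with
# read-pair alignments, an unmapped-read pool and de novo contigs; every
# degradation is recorded in a truth ledger.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' two stages (PVS, Egg) with two replicates each, 200 multi-exon genes,
#' 10\% of genes dropped from the reference, UTR truncations at both ends,
#' NB counts with dispersion 0.05 and 10\% of genes carrying a planted
#' |log2 fold-change| of 2, a transposon landscape dominated by
#' Tc1-mariner/Helitron-like classes, and an unmapped pool mixing dropped
#' genes with poly-A and low-GC junk reads.
#'
#' @param seed integer seed; fixing it makes every generator output
#'   byte-identical across runs.
#' @param n_contigs,contig_length genome shape.
#' @param gc genome GC content in `[0,1]`.
#' @param n_genes number of genes to place.
#' @param p_second_isoform probability a gene carries a second,
#'   exon-skipping isoform.
#' @param p_drop_gene,p_drop_isoform reference degradation probabilities.
#' @param p_truncate_5p,p_truncate_3p probability of a UTR truncation at
#'   each gene end; lengths are uniform on `truncation_range` (bp).
#' @param truncation_range length-2 numeric, truncation draw range in bp.
#' @param mean_log,sd_log log-normal parameters of per-transcript baseline
#'   expression means.
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param p_de,de_log2fc fraction of genes with planted differential
#'   expression and the planted |log2 fold-change| (up = higher in Egg).
#' @param capture_rate fraction of a transcript's read pairs captured as
#'   assembly support.
#' @param noise_transfrag_rate fraction (of expressed transcripts) of junk
#'   transfrags injected with support below the acceptance threshold.
#' @param repeat_classes data.frame with columns `class`, `copies`,
#'   `min_len`, `max_len` describing the repeat landscape.
#' @param repeat_overlap_frac fraction of repeat copies placed overlapping
#'   a previous same-class, same-strand copy (exercises merging).
#' @param pairs_per_copy expected aligned pairs per repeat copy per sample.
#' @param p_multi,p_cross_class,p_unassigned multi-mapping rate, rate of
#'   cross-class (ambiguous) placements, and rate of pairs placed outside
#'   any feature.
#' @param polyA_fraction,lowgc_fraction junk-read fractions of the
#'   unmapped pool; must sum to less than 1.
#' @param reads_per_dropped_tx unmapped-pool reads drawn per dropped
#'   transcript.
#' @param read_length unmapped-pool read length (nt).
#' @param min_aa minimum ORF length (codons) the planted CDSs guarantee.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L, contig_length = 300000L, gc = 0.42,
                       n_genes = 200L,
                       p_second_isoform = 0.3,
                       p_drop_gene = 0.1, p_drop_isoform = 0.1,
                       p_truncate_5p = 0.5, p_truncate_3p = 0.5,
                       truncation_range = c(50, 450),
                       mean_log = log(300), sd_log = 1,
                       dispersion = 0.05,
                       p_de = 0.1, de_log2fc = 2,
                       capture_rate = 0.8,
                       noise_transfrag_rate = 0.05,
                       repeat_classes = data.frame(
                         class = c("Tc1-mariner", "Helitron", "Tc1",
                                   "Unknown", "Satellite"),
                         copies = c(12L, 8L, 6L, 6L, 4L),
                         min_len = 300, max_len = 1500,
                         stringsAsFactors = FALSE),
                       repeat_overlap_frac = 0.3,
                       pairs_per_copy = 20,
                       p_multi = 0.3, p_cross_class = 0.03,
                       p_unassigned = 0.05,
                       polyA_fraction = 0.15, lowgc_fraction = 0.15,
                       reads_per_dropped_tx = 40L,
                       read_length = 100L,
                       min_aa = 100L) {
  cfg <- as.list(environment())
  probs <- c(p_second_isoform = p_second_isoform, p_drop_gene = p_drop_gene,
             p_drop_isoform = p_drop_isoform, p_truncate_5p = p_truncate_5p,
             p_truncate_3p = p_truncate_3p, p_de = p_de, gc = gc,
             capture_rate = capture_rate, polyA_fraction = polyA_fraction,
             lowgc_fraction = lowgc_fraction)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0,1]")
  if (polyA_fraction + lowgc_fraction > 1)
    stop("config error: junk fractions sum above 1")
  if (dispersion <= 0) stop("config error: dispersion must be positive")
  if (n_contigs < 0 || contig_length <= 0 && n_contigs > 0)
    stop("config error: non-positive contig length")
  class(cfg) <- "sim_config"
  cfg
}

.sample_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.rand_seq <- function(n, gc) paste(.sample_bases(n, gc), collapse = "")

#' Generate a random genome
#'
#' @param config a [sim_config()].
#' @return named character vector of contig sequences
#'   (`contig_1`, ..., `contig_n`), i.i.d. bases at the configured GC,
#'   deterministic under the config seed.
#' @export
generate_genome <- function(config) {
  if (config$n_contigs == 0L) return(setNames(character(0), character(0)))
  set.seed(config$seed + 11L)
  seqs <- vapply(seq_len(config$n_contigs), function(i)
    .rand_seq(config$contig_length, config$gc), "")
  setNames(seqs, paste0("contig_", seq_len(config$n_contigs)))
}

# codons used for CDS bodies: all codons except stops and ATG, so the
# planted CDS is the unique in-frame ORF and its truth label is unambiguous
.body_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA", "ATG"))
})

.stop_codons <- c("TAA", "TAG", "TGA")

# quick scan used only for generator-side rejection: positions of maximal
# ORFs >= min_aa in the three forward frames of a spliced sequence
.orf_signature <- function(seq, min_aa) {
  calls <- find_orfs(seq, min_aa = min_aa, strands = "forward")
  if (nrow(calls) == 0L) return(character(0))
  sprintf("%s:%d-%d", calls$completeness, calls$start, calls$end)
}

# build the spliced sequence of one transcript: utr5 | ATG body stop | utr3
# with rejection so the annotated CDS is the only reported ORF; when a
# skipped-exon isoform exists (`skip` = spliced 0-based window removed by
# the variant), its sequence must carry no reportable ORF at all, so the
# gene's ORF truth is carried by the primary isoform alone
.make_tx_sequence <- function(utr5, cds_codons, utr3, gc, min_aa,
                              skip = NULL) {
  for (try in 1:60) {
    body <- paste(sample(.body_codons, cds_codons - 2L, replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", body, sample(.stop_codons, 1L))
    seq <- paste0(.rand_seq(utr5, gc), cds, .rand_seq(utr3, gc))
    sig <- .orf_signature(seq, min_aa)
    want <- sprintf("complete:%d-%d", utr5, utr5 + cds_codons * 3L)
    if (!identical(sig, want)) next
    if (!is.null(skip)) {
      # the exon-skipping variant frameshifts downstream of `skip`; it
      # must not encode its own complete ORF, which would mask the
      # primary isoform's completeness truth after 3' truncations
      seq2 <- paste0(substring(seq, 1L, skip[1L]),
                     substring(seq, skip[2L] + 1L, nchar(seq)))
      if (any(startsWith(.orf_signature(seq2, min_aa), "complete"))) next
    }
    return(seq)
  }
  stop("placement error: could not build an unambiguous CDS sequence")
}

#' Generate a truth annotation and its degraded reference
#'
#' Places non-overlapping multi-exon genes (5'UTR, CDS of at least
#' `min_aa` codons, 3'UTR) on the genome, patches the genome so every
#' transcript actually encodes its planted ORF, then derives the
#' "reference" annotation by dropping genes/isoforms and truncating
#' terminal exons, recording every degradation in the ledger. Truncations
#' are confined to terminal exons, so spliced and genome-projected
#' truncation amounts coincide; truncations entering the CDS always leave
#' at least `min_aa` codons.
#'
#' @param genome output of [generate_genome()].
#' @param config a [sim_config()].
#' @return list with elements `truth` (transcript models), `reference`
#'   (degraded models), `ledger` (truth ledger) and `genome` (the patched
#'   genome the annotations refer to).
#' @export
generate_annotation_pair <- function(genome, config) {
  set.seed(config$seed + 23L)
  n <- config$n_genes
  min_aa <- config$min_aa
  truth <- list()
  gene_meta <- list()
  # sequential placement across contigs
  ctg_i <- 1L
  cursor <- 200L
  for (g in seq_len(n)) {
    utr5 <- sample(100:300, 1L)
    utr3 <- sample(150:400, 1L)
    codons <- sample(140:220, 1L)
    e1c <- sample(60:150, 1L)   # CDS bp inside first exon
    e3c <- sample(60:150, 1L)   # CDS bp inside last exon
    cds_nt <- codons * 3L
    inner <- cds_nt - e1c - e3c
    two_iso <- runif(1) < config$p_second_isoform
    n_mid <- if (two_iso) 2L else sample(1:2, 1L)
    # split inner CDS bp across middle exons (each >= 30 bp); for
    # two-isoform genes the skipped exon length must not be a multiple of
    # 3, so the exon-skipping variant frameshifts instead of encoding a
    # shorter in-frame protein
    if (n_mid == 1L) mids <- inner
    else {
      # for two-isoform genes keep the pre-skip CDS under 100 codons so a
      # frameshifted stop can terminate the variant's ORF early enough
      hi <- if (two_iso) max(min(inner - 33L, 270L - e1c), 30L)
      else inner - 33L
      cut <- sample(30:hi, 1L)
      if ((inner - cut) %% 3L == 0L) cut <- cut + 1L
      mids <- c(cut, inner - cut)
    }
    ex_lens <- c(utr5 + e1c, mids, e3c + utr3)
    introns <- sample(80:300, length(ex_lens) - 1L, replace = TRUE)
    glen <- sum(ex_lens) + sum(introns)
    if (cursor + glen + 200L > config$contig_length) {
      ctg_i <- ctg_i + 1L
      cursor <- 200L
      if (ctg_i > config$n_contigs)
        stop("placement error: genome too short to place ", n, " genes")
    }
    contig <- paste0("contig_", ctg_i)
    starts <- cursor + cumsum(c(0L, head(ex_lens, -1L) + introns))
    exons <- cbind(starts, starts + ex_lens)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("SG%06d", g)
    # spliced CDS occupies [utr5, utr5 + cds_nt); for two-isoform genes
    # the skipped segment is middle exon 2
    skip <- if (two_iso)
      c(ex_lens[1L] + ex_lens[2L], ex_lens[1L] + ex_lens[2L] + ex_lens[3L])
    seq <- .make_tx_sequence(utr5, codons, utr3, config$gc, min_aa,
                             skip = skip)
    # patch genome (strand-aware) so exon concatenation yields `seq`
    gseq <- if (strand == "+") seq else revcomp(seq)
    s <- genome[[contig]]
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      w <- exons[i, 2L] - exons[i, 1L]
      substr(s, exons[i, 1L] + 1L, exons[i, 2L]) <-
        substr(gseq, off + 1L, off + w)
      off <- off + w
    }
    genome[[contig]] <- s
    cds_spliced <- c(utr5, utr5 + cds_nt)
    cds_geno <- .spliced_to_genomic(exons, strand, cds_spliced)
    txA <- transcript_model(paste0(gid, ".t1"), gid, contig, strand,
                            exons, cds = cds_geno)
    txs <- list(txA)
    if (two_iso) {
      # isoform B skips the second middle exon (index 3 of >= 4 exons)
      exB <- exons[-3L, , drop = FALSE]
      txs <- c(txs, list(transcript_model(paste0(gid, ".t2"), gid, contig,
                                          strand, exB)))
    }
    truth <- c(truth, txs)
    gene_meta[[gid]] <- list(utr5 = utr5, utr3 = utr3, codons = codons,
                             exons = exons, strand = strand, contig = contig,
                             two_iso = two_iso)
    cursor <- cursor + glen + sample(300:800, 1L)
  }

  # --- degradation ---------------------------------------------------
  gids <- names(gene_meta)
  dropped_genes <- gids[runif(length(gids)) < config$p_drop_gene]
  two_iso_g <- gids[vapply(gene_meta, `[[`, TRUE, "two_iso")]
  cand <- setdiff(two_iso_g, dropped_genes)
  dropped_iso <- paste0(cand[runif(length(cand)) < config$p_drop_isoform],
                        ".t2")
  trunc <- data.frame(gene_id = character(0), five_prime_bp = numeric(0),
                      three_prime_bp = numeric(0), stringsAsFactors = FALSE)
  cds_trunc_5p <- character(0)
  cds_trunc_3p <- character(0)
  orf_truth <- data.frame(transcript_id = character(0),
                          completeness = character(0),
                          stringsAsFactors = FALSE)
  reference <- list()
  for (m in truth) {
    gid <- m$gene_id
    if (gid %in% dropped_genes) next
    if (m$transcript_id %in% dropped_iso) next
    meta <- gene_meta[[gid]]
    tr <- trunc[trunc$gene_id == gid, ]
    if (nrow(tr) == 0L) {
      t5 <- t3 <- 0
      budget <- 3L * (meta$codons - config$min_aa - 5L)  # CDS bp to spare
      if (runif(1) < config$p_truncate_5p)
        t5 <- .cap_truncation(sample(config$truncation_range[1L]:
                                       config$truncation_range[2L], 1L),
                              meta$utr5, budget,
                              meta$exons, meta$strand, five_prime = TRUE)
      if (runif(1) < config$p_truncate_3p)
        t3 <- .cap_truncation(sample(config$truncation_range[1L]:
                                       config$truncation_range[2L], 1L),
                              meta$utr3,
                              budget - 3L * ceiling(max(t5 - meta$utr5, 0) / 3),
                              meta$exons, meta$strand, five_prime = FALSE)
      trunc <- rbind(trunc, data.frame(gene_id = gid, five_prime_bp = t5,
                                       three_prime_bp = t3,
                                       stringsAsFactors = FALSE))
      if (t5 > meta$utr5) cds_trunc_5p <- c(cds_trunc_5p, gid)
      if (t3 > meta$utr3) cds_trunc_3p <- c(cds_trunc_3p, gid)
    } else {
      t5 <- tr$five_prime_bp
      t3 <- tr$three_prime_bp
    }
    reference <- c(reference, list(.truncate_model(m, t5, t3)))
    if (m$transcript_id == paste0(gid, ".t1")) {
      lab <- if (t5 > meta$utr5 && t3 > meta$utr3) "internal"
      else if (t5 > meta$utr5) "5prime_partial"
      else if (t3 > meta$utr3) "3prime_partial"
      else "complete"
      orf_truth <- rbind(orf_truth,
                         data.frame(transcript_id = m$transcript_id,
                                    completeness = lab,
                                    stringsAsFactors = FALSE))
    }
  }
  trunc <- trunc[trunc$five_prime_bp > 0 | trunc$three_prime_bp > 0, ,
                 drop = FALSE]
  ledger <- list(dropped_genes = dropped_genes,
                 dropped_isoforms = dropped_iso,
                 truncations = trunc,
                 cds_truncated_5p = cds_trunc_5p,
                 cds_truncated_3p = cds_trunc_3p,
                 orf_truth = orf_truth,
                 planted_de = NULL, repeat_copies = NULL,
                 noise_transfrags = character(0))
  list(truth = truth, reference = reference, ledger = ledger,
       genome = genome)
}

# map a spliced interval to genomic CDS segments
.spliced_to_genomic <- function(exons, strand, iv) {
  lens <- exons[, 2L] - exons[, 1L]
  if (strand == "-") {
    # spliced coordinates run along the transcript 5'->3'; on the minus
    # strand that is right-to-left across exons in genome order
    ord <- rev(seq_len(nrow(exons)))
  } else ord <- seq_len(nrow(exons))
  segs <- NULL
  off <- 0
  for (i in ord) {
    w <- lens[i]
    a <- max(iv[1L], off); b <- min(iv[2L], off + w)
    if (a < b) {
      if (strand == "+") seg <- c(exons[i, 1L] + (a - off),
                                  exons[i, 1L] + (b - off))
      else seg <- c(exons[i, 2L] - (b - off), exons[i, 2L] - (a - off))
      segs <- rbind(segs, seg)
    }
    off <- off + w
  }
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  .as_interval_matrix(segs)
}

# cap a drawn truncation so it (a) stays within the terminal exon, (b) if
# it enters the CDS, removes at least 6 bp of it and stays within the
# remaining CDS budget (`budget_nt`, the CDS bp that may be lost while
# still leaving >= min_aa + 5 codons after BOTH ends are cut)
.cap_truncation <- function(t, utr, budget_nt, exons, strand, five_prime) {
  term_len <- if ((strand == "+") == five_prime)
    exons[1L, 2L] - exons[1L, 1L] else exons[nrow(exons), 2L] - exons[nrow(exons), 1L]
  t <- min(t, term_len - 30L)
  t <- min(t, utr + max(budget_nt, 0L))
  if (t > utr && t < utr + 6L) t <- utr
  max(t, 0L)
}

# trim t5 spliced bp from the 5' end and t3 from the 3' end (both within
# terminal exons by construction); clip CDS segments accordingly
.truncate_model <- function(m, t5, t3) {
  ex <- m$exons
  n <- nrow(ex)
  if (m$strand == "+") {
    ex[1L, 1L] <- ex[1L, 1L] + t5
    ex[n, 2L] <- ex[n, 2L] - t3
  } else {
    ex[n, 2L] <- ex[n, 2L] - t5
    ex[1L, 1L] <- ex[1L, 1L] + t3
  }
  cds <- m$cds
  if (!is.null(cds)) {
    cds[, 1L] <- pmax(cds[, 1L], ex[1L, 1L])
    cds[, 2L] <- pmin(cds[, 2L], ex[n, 2L])
    cds <- cds[cds[, 2L] > cds[, 1L], , drop = FALSE]
    if (nrow(cds) == 0L) cds <- NULL
  }
  transcript_model(m$transcript_id, m$gene_id, m$contig, m$strand, ex,
                   cds = cds, attributes = m$attributes)
}

#' Simulate NB counts for the truth transcripts
#'
#' Counts follow NegativeBinomial(mu, dispersion) with per-transcript
#' baseline means drawn log-normally; genes planted as differentially
#' expressed have their Egg-condition mean scaled by `2^log2fc`
#' ("up" = higher in Egg).
#'
#' @param truth list of truth transcript models.
#' @param config a [sim_config()].
#' @param ledger optional ledger to extend with the `planted_de` record.
#' @return list with `counts` (transcripts x samples matrix, columns
#'   `PVS_1`, `PVS_2`, `Egg_1`, `Egg_2`), `meta` (sample metadata) and
#'   `ledger`.
#' @export
simulate_counts <- function(truth, config, ledger = list()) {
  if (config$dispersion <= 0) stop("config error: dispersion must be positive")
  set.seed(config$seed + 37L)
  txids <- model_ids(truth)
  gids <- model_genes(truth)
  ugenes <- unique(gids)
  base <- exp(rnorm(length(txids), config$mean_log, config$sd_log))
  de_genes <- ugenes[runif(length(ugenes)) < config$p_de]
  dir <- sample(c("up", "down"), length(de_genes), replace = TRUE)
  lfc <- setNames(rep(0, length(ugenes)), ugenes)
  lfc[de_genes] <- ifelse(dir == "up", config$de_log2fc, -config$de_log2fc)
  mu_pvs <- base
  mu_egg <- base * 2 ^ lfc[gids]
  size <- 1 / config$dispersion
  samples <- c("PVS_1", "PVS_2", "Egg_1", "Egg_2")
  counts <- cbind(
    PVS_1 = rnbinom(length(base), mu = mu_pvs, size = size),
    PVS_2 = rnbinom(length(base), mu = mu_pvs, size = size),
    Egg_1 = rnbinom(length(base), mu = mu_egg, size = size),
    Egg_2 = rnbinom(length(base), mu = mu_egg, size = size))
  rownames(counts) <- txids
  meta <- data.frame(sample = samples,
                     condition = c("PVS", "PVS", "Egg", "Egg"),
                     replicate = c(1L, 2L, 1L, 2L),
                     stringsAsFactors = FALSE)
  ledger$planted_de <- data.frame(gene_id = de_genes, direction = dir,
                                  log2fc = abs(lfc[de_genes]),
                                  stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, ledger = ledger)
}

#' Simulate assembled transfrags from truth transcripts
#'
#' Every expressed truth transcript (including those dropped from the
#' reference) yields one transfrag with the exact truth exon structure,
#' support read-pairs equal to the captured fraction of its counts, and
#' per-condition abundances. A configurable fraction of noise transfrags
#' with support below 20 is injected.
#'
#' @param truth truth transcript models.
#' @param counts transcript count matrix from [simulate_counts()].
#' @param config a [sim_config()].
#' @param ledger optional ledger to extend.
#' @return list with `transfrags` (list of transfrag records: `model`,
#'   `support_pairs`, `abundance`) and `ledger` (gains
#'   `noise_transfrags` and `expressed_transcripts`).
#' @export
simulate_transfrags <- function(truth, counts, config, ledger = list()) {
  set.seed(config$seed + 41L)
  txids <- model_ids(truth)
  total <- rowSums(counts)[txids]
  expressed <- txids[total > 0]
  tfs <- list()
  k <- 0L
  for (m in truth) {
    tot <- total[[m$transcript_id]]
    if (is.na(tot) || tot == 0) next
    k <- k + 1L
    support <- as.integer(round(config$capture_rate * tot))
    ab <- c(PVS = sum(counts[m$transcript_id, c("PVS_1", "PVS_2")]),
            Egg = sum(counts[m$transcript_id, c("Egg_1", "Egg_2")]))
    tfm <- transcript_model(sprintf("TCONS_%05d", k), sprintf("TLOC_%05d", k),
                            m$contig, m$strand, m$exons,
                            attributes = c(source_tx = m$transcript_id))
    tfs[[length(tfs) + 1L]] <- transfrag(tfm, support, ab)
  }
  n_noise <- round(config$noise_transfrag_rate * length(tfs))
  noise_ids <- character(0)
  if (n_noise > 0) {
    for (i in seq_len(n_noise)) {
      k <- k + 1L
      contig <- paste0("contig_", sample(config$n_contigs, 1L))
      st <- sample(1000:(config$contig_length - 2000L), 1L)
      id <- sprintf("TCONS_%05d", k)
      tfm <- transcript_model(id, sprintf("TLOC_%05d", k), contig,
                              sample(c("+", "-"), 1L),
                              cbind(st, st + sample(200:800, 1L)))
      tfs[[length(tfs) + 1L]] <- transfrag(tfm, sample(1:19, 1L),
                                           c(PVS = 3, Egg = 3))
      noise_ids <- c(noise_ids, id)
    }
  }
  ledger$noise_transfrags <- noise_ids
  ledger$expressed_transcripts <- expressed
  list(transfrags = tfs, ledger = ledger)
}

#' Construct a transfrag record
#'
#' @param model a [transcript_model()].
#' @param support_pairs read-pair support of the assembly.
#' @param abundance named numeric, per-condition estimated counts.
#' @return object of class `"transfrag"`.
#' @export
transfrag <- function(model, support_pairs, abundance) {
  if (support_pairs < 0 || any(abundance < 0))
    stop("integrity error: negative transfrag support/abundance")
  structure(list(model = model, support_pairs = support_pairs,
                 abundance = abundance, cpm = NULL), class = "transfrag")
}

#' @export
print.transfrag <- function(x, ...) {
  cat(sprintf("<transfrag> %s support=%d abundance=(%s)\n",
              x$model$transcript_id, x$support_pairs,
              paste(names(x$abundance), round(x$abundance, 1), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a repeat landscape and its read-pair alignments
#'
#' Places copies of each configured repeat class on both strands, a
#' fraction overlapping within class to exercise merging, and generates
#' paired alignments per copy with configurable multi-mapping, cross-class
#' (ambiguous) placements, and feature-free (unassigned) pairs.
#'
#' @param genome genome sequences (only contig names/lengths are used).
#' @param config a [sim_config()].
#' @param ledger optional ledger to extend.
#' @param avoid optional data.frame of intervals (`contig`, `start`,
#'   `end`) that fresh copies must not overlap — typically the gene
#'   spans, mirroring the predominantly intergenic location of repeat
#'   annotation relative to gene models.
#' @return list with `features` (repeat feature data.frame), `alignments`
#'   (alignment data.frame over samples PVS_1..Egg_2) and `ledger`
#'   (gains `repeat_copies` and `repeat_clusters`).
#' @export
simulate_repeat_landscape <- function(genome, config, ledger = list(),
                                      avoid = NULL) {
  set.seed(config$seed + 53L)
  rc <- config$repeat_classes
  feats <- NULL
  fid <- 0L
  clear_of <- function(iv, contig, start, end) {
    if (is.null(iv) || nrow(iv) == 0L) return(TRUE)
    sub <- iv[iv$contig == contig, , drop = FALSE]
    !any(sub$start < end & start < sub$end)
  }
  for (i in seq_len(nrow(rc))) {
    prev <- NULL
    ncp <- rc$copies[i]
    if (ncp == 0L) next
    for (j in seq_len(ncp)) {
      fid <- fid + 1L
      len <- sample(rc$min_len[i]:rc$max_len[i], 1L)
      if (!is.null(prev) && runif(1) < config$repeat_overlap_frac) {
        contig <- prev$contig; strand <- prev$strand
        start <- prev$start + sample(seq_len(max(prev$end - prev$start - 50L,
                                                 1L)), 1L)
      } else {
        # fresh copies avoid gene spans and copies of other classes, so
        # geometric cross-class ambiguity stays controlled by the
        # multi-mapping rate rather than by placement accidents
        other <- feats[feats$repeat_class != rc$class[i], , drop = FALSE]
        for (try in 1:80) {
          contig <- paste0("contig_", sample(config$n_contigs, 1L))
          strand <- sample(c("+", "-"), 1L)
          start <- sample(1000:(config$contig_length - rc$max_len[i] -
                                  1000L), 1L)
          if (clear_of(avoid, contig, start, start + len) &&
              clear_of(other, contig, start, start + len)) break
        }
      }
      row <- data.frame(feature_id = sprintf("RF%04d", fid), contig = contig,
                        start = start, end = start + len, strand = strand,
                        repeat_class = rc$class[i], family = rc$class[i],
                        stringsAsFactors = FALSE)
      feats <- rbind(feats, row)
      prev <- row
    }
  }
  # generator-side record of mergeable same-class/strand clusters
  clusters <- list()
  for (key in unique(paste(feats$repeat_class, feats$contig, feats$strand))) {
    sub <- feats[paste(feats$repeat_class, feats$contig, feats$strand) == key, ]
    sub <- sub[order(sub$start), ]
    grp <- cumsum(c(TRUE, sub$start[-1L] >= cummax(sub$end[-nrow(sub)])))
    for (g in split(sub$feature_id, grp))
      clusters[[length(clusters) + 1L]] <- g
  }
  samples <- c("PVS_1", "PVS_2", "Egg_1", "Egg_2")
  aln <- NULL
  pid <- 0L
  by_class <- split(seq_len(nrow(feats)), feats$repeat_class)
  place_in <- function(f) {
    # one pair: two mates of 75 nt inside feature f
    w <- feats$end[f] - feats$start[f]
    p <- feats$start[f] + sample(0:max(w - 160L, 0L), 1L)
    sprintf("%d-%d;%d-%d", p, p + 75L, p + 85L, p + 160L)
  }
  for (s in samples) {
    for (f in seq_len(nrow(feats))) {
      np <- rpois(1L, config$pairs_per_copy)
      for (q in seq_len(np)) {
        pid <- pid + 1L
        id <- sprintf("rp%07d", pid)
        placements <- f
        resample <- function(x, n) x[sample.int(length(x), n)]
        if (runif(1) < config$p_multi) {
          same <- setdiff(by_class[[feats$repeat_class[f]]], f)
          if (length(same))
            placements <- c(f, resample(same, min(length(same),
                                                  sample(1:3, 1L))))
        }
        if (runif(1) < config$p_cross_class) {
          other <- setdiff(seq_len(nrow(feats)),
                           by_class[[feats$repeat_class[f]]])
          if (length(other))
            placements <- c(placements, resample(other, 1L))
        }
        nh <- length(placements)
        for (f2 in placements)
          aln <- rbind(aln, data.frame(
            pair_id = id, sample = s, contig = feats$contig[f2],
            strand = feats$strand[f2], blocks = place_in(f2), n_hits = nh,
            both_ends_aligned = TRUE, same_contig_strand = TRUE,
            stringsAsFactors = FALSE))
      }
    }
    # feature-free pairs
    n_un <- rpois(1L, config$p_unassigned * nrow(feats) *
                    config$pairs_per_copy)
    for (q in seq_len(n_un)) {
      pid <- pid + 1L
      p <- sample(seq(config$contig_length - 2000L, config$contig_length -
                        500L), 1L)
      aln <- rbind(aln, data.frame(
        pair_id = sprintf("rp%07d", pid), sample = s,
        contig = paste0("contig_", sample(config$n_contigs, 1L)),
        strand = "+", blocks = sprintf("%d-%d;%d-%d", p, p + 75L, p + 85L,
                                       p + 160L),
        n_hits = 1L, both_ends_aligned = TRUE, same_contig_strand = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  rownames(feats) <- NULL
  ledger$repeat_copies <- lapply(by_class, function(ix) feats$feature_id[ix])
  ledger$repeat_clusters <- clusters
  list(features = feats, alignments = aln, ledger = ledger)
}

#' Simulate the unmapped-read pool
#'
#' Draws reads from dropped-gene transcripts, plus poly-A/T-tailed junk
#' and low-GC junk, with read-id prefixes (`drop_`, `polyA_`, `lowgc_`)
#' partitioning the pool into its source categories.
#'
#' @param truth truth transcript models.
#' @param ledger ledger holding `dropped_genes`.
#' @param genome patched genome sequences.
#' @param config a [sim_config()].
#' @return named character vector of reads.
#' @export
simulate_unmapped_pool <- function(truth, ledger, genome, config) {
  if (config$polyA_fraction + config$lowgc_fraction > 1)
    stop("config error: junk fractions sum above 1")
  set.seed(config$seed + 67L)
  dropped <- truth[model_genes(truth) %in% ledger$dropped_genes]
  reads <- character(0)
  for (m in dropped) {
    seq <- tx_sequence(m, genome)
    L <- nchar(seq)
    rl <- min(config$read_length, L)
    for (i in seq_len(config$reads_per_dropped_tx)) {
      st <- sample(seq_len(max(L - rl + 1L, 1L)), 1L)
      reads[paste0("drop_", m$transcript_id, "_", i)] <-
        substring(seq, st, st + rl - 1L)
    }
  }
  nd <- length(reads)
  pj <- config$polyA_fraction + config$lowgc_fraction
  n_total <- if (pj < 1 && nd > 0) round(nd / (1 - pj))
  else if (nd == 0 && pj == 0) 0L else max(nd, 20L)
  n_polyA <- round(config$polyA_fraction * n_total)
  n_lowgc <- round(config$lowgc_fraction * n_total)
  for (i in seq_len(n_polyA)) {
    core <- .rand_seq(sample(40:120, 1L), config$gc)
    tail <- strrep(sample(c("A", "T"), 1L), sample(5:20, 1L))
    reads[paste0("polyA_", i)] <- if (substr(tail, 1, 1) == "T" &&
                                      runif(1) < 0.5)
      paste0(tail, core) else paste0(core, tail)
  }
  for (i in seq_len(n_lowgc)) {
    repeat {
      s <- .rand_seq(sample(40:120, 1L), 0.1)
      gcf <- .gc_content(s)
      if (gcf <= 0.2) break
    }
    reads[paste0("lowgc_", i)] <- s
  }
  reads
}

.gc_content <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n == 0L, 0, gc / n)
}

#' Simulate de novo contigs for the rescue stage
#'
#' Builds stage-specific contig sets from the dropped-gene transcripts
#' (the signal the de novo route should recover), adds near-duplicate
#' copies to exercise deduplication and low-abundance junk contigs from
#' the poly-A/low-GC pools. TPM is computed within each stage's contig
#' pool.
#'
#' @param truth truth models; `counts` the transcript count matrix;
#'   `ledger` with `dropped_genes`; `genome` patched genome;
#'   `config` a [sim_config()].
#' @param counts,ledger,genome,config see above.
#' @return data.frame of contig records: `contig_id`, `stage`, `sequence`,
#'   `tpm`, `estimated_reads`, `source` (truth label).
#' @export
simulate_denovo_contigs <- function(truth, counts, ledger, genome, config) {
  set.seed(config$seed + 71L)
  # contigs come from the CDS-bearing primary isoforms; the frameshifted
  # exon-skipping variants carry no coding truth to recover
  dropped <- truth[model_genes(truth) %in% ledger$dropped_genes &
                     !vapply(truth, function(m) is.null(m$cds), TRUE)]
  out <- NULL
  for (stage in c("PVS", "Egg")) {
    cols <- grep(paste0("^", stage), colnames(counts))
    recs <- NULL
    for (m in dropped) {
      cnt <- sum(counts[m$transcript_id, cols])
      if (cnt == 0) next
      seq <- tx_sequence(m, genome)
      est <- config$capture_rate * cnt
      recs <- rbind(recs, data.frame(
        contig_id = paste0(stage, "_", m$transcript_id),
        stage = stage, sequence = seq, estimated_reads = est,
        source = m$transcript_id, stringsAsFactors = FALSE))
      if (runif(1) < 0.3) {
        # near-duplicate (about 1% of positions mutated, slightly shorter)
        dup <- .mutate_seq(substring(seq, 1L, round(nchar(seq) * 0.9)), 0.01)
        recs <- rbind(recs, data.frame(
          contig_id = paste0(stage, "_", m$transcript_id, "_dup"),
          stage = stage, sequence = dup, estimated_reads = est * 0.2,
          source = m$transcript_id, stringsAsFactors = FALSE))
      }
    }
    # junk contigs: low abundance, non-coding
    for (i in seq_len(5L)) {
      recs <- rbind(recs, data.frame(
        contig_id = sprintf("%s_junk%02d", stage, i), stage = stage,
        sequence = .rand_seq(sample(300:600, 1L), 0.42),
        estimated_reads = sample(3:15, 1L), source = "junk",
        stringsAsFactors = FALSE))
    }
    if (is.null(recs)) next
    lens <- nchar(recs$sequence)
    rate <- recs$estimated_reads / lens
    recs$tpm <- rate / sum(rate) * 1e6
    out <- rbind(out, recs)
  }
  rownames(out) <- NULL
  out
}

.mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  ix <- which(runif(length(ch)) < rate)
  for (i in ix) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Run the full generator
#'
#' Convenience wrapper calling every simulation stage in order and
#' returning all artifacts plus the completed truth ledger.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `truth`, `reference`, `counts`, `meta`,
#'   `transfrags`, `repeats` (features + alignments), `unmapped_reads`,
#'   `contigs`, `ledger`, `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  genome0 <- generate_genome(config)
  ann <- generate_annotation_pair(genome0, config)
  cnt <- simulate_counts(ann$truth, config, ann$ledger)
  tfs <- simulate_transfrags(ann$truth, cnt$counts, config, cnt$ledger)
  rep <- simulate_repeat_landscape(ann$genome, config, tfs$ledger,
                                   avoid = gene_spans(ann$truth))
  pool <- simulate_unmapped_pool(ann$truth, rep$ledger, ann$genome, config)
  contigs <- simulate_denovo_contigs(ann$truth, cnt$counts, rep$ledger,
                                     ann$genome, config)
  list(genome = ann$genome, truth = ann$truth, reference = ann$reference,
       counts = cnt$counts, meta = cnt$meta, transfrags = tfs$transfrags,
       repeats = rep[c("features", "alignments")], unmapped_reads = pool,
       contigs = contigs, ledger = rep$ledger, config = config)
}

#' Write / read the truth ledger as JSON
#' @param ledger truth ledger list.
#' @param file path.
#' @return `file` invisibly / the ledger list.
#' @export
write_ledger <- function(ledger, file) {
  jsonlite::write_json(ledger, file, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(file) {
  l <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("truncations", "orf_truth", "planted_de"))
    if (!is.null(l[[nm]])) l[[nm]] <- as.data.frame(l[[nm]],
                                                    stringsAsFactors = FALSE)
  l
}
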
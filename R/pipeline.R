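# End-to-end orchestration: simulate -> compare -> orfs -> rescue ->
# repeats -> de -> enrich, with one threshold profile and a
# machine-readable run report.

#' Default analysis thresholds
#'
#' One auditable place for every stage threshold: 20 supporting pairs
#' per transfrag, 40-pair expressed-gene cutoff, isoform fraction 0.4,
#' CPM > 1, TPM >= 10, 95\% clustering identity, 100 aa minimum ORF,
#' repeat regions > 500 bp, |fold-change| >= 2.5 at adjusted p <= 0.01,
#' and enrichment FDR 0.05.
#'
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(min_support = 20, expressed_cutoff = 40, min_isoform_fraction = 0.4,
       min_cpm = 1, min_tpm = 10, min_reads = 20, identity = 0.95,
       min_aa = 100L, min_region_bp = 500, fc = 2.5, padj = 0.01,
       enrich_fdr = 0.05, top_k = 25)
}

# per-condition CPM of transfrag abundances
.transfrag_cpm <- function(transfrags) {
  ab <- t(vapply(transfrags, `[[`, c(PVS = 0, Egg = 0), "abundance"))
  rownames(ab) <- vapply(transfrags, function(t) t$model$transcript_id, "")
  tot <- colSums(ab)
  tot[tot == 0] <- 1
  sweep(ab, 2L, tot, "/") * 1e6
}

# extract a per-class repeat consensus library from the genome
.repeat_library <- function(features, genome) {
  lib <- character(0)
  for (cl in unique(features$repeat_class)) {
    sub <- features[features$repeat_class == cl, , drop = FALSE]
    i <- which.max(sub$end - sub$start)
    s <- substring(genome[[sub$contig[i]]], sub$start[i] + 1L, sub$end[i])
    if (sub$strand[i] == "-") s <- revcomp(s)
    lib[cl] <- s
  }
  lib
}

# synthetic term map over a gene universe: random terms plus terms seeded
# with the planted DE genes so the enrichment stage has signal
.make_term_map <- function(universe, planted_up, planted_down, seed) {
  set.seed(seed + 83L)
  tm <- list()
  for (i in 1:20)
    tm[[sprintf("TERM_%03d", i)]] <- sample(universe,
                                            min(sample(10:30, 1L),
                                                length(universe)))
  pad <- function(g) unique(c(g, sample(universe, 5L)))
  if (length(planted_up)) tm[["TERM_UP"]] <- pad(planted_up)
  if (length(planted_down)) tm[["TERM_DOWN"]] <- pad(planted_down)
  tm
}

#' Run the full pipeline on simulated data
#'
#' Executes every stage in order against one generated experiment and
#' returns a run report whose counts equal the corresponding output
#' record counts. Rerunning with the same config yields an identical
#' report (stage timings are returned in the R object but kept out of
#' the JSON report so reruns are byte-identical).
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory; when given, all artifacts
#'   (GTF/FASTA/TSV/JSON) are written there.
#' @param thresholds list from [pipeline_thresholds()].
#' @param term_map optional named list term -> gene ids; when absent a
#'   synthetic map seeded with the planted DE genes is used.
#' @return list of class `"txforge_run"`: `report`, `timings`, plus the
#'   stage outputs (`calls`, `accepted_isoforms`, `novel_loci`,
#'   `extensions`, `orf_report`, `rescued`, `repeat_quant`,
#'   `de_results`, `top_tables`, `enrichment`, `sim`).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         thresholds = pipeline_thresholds(),
                         term_map = NULL) {
  th <- utils::modifyList(pipeline_thresholds(), thresholds)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  sim <- simulate_experiment(config)
  timings["simulate"] <- tic() - t0

  # --- compare -------------------------------------------------------
  t0 <- tic()
  idx <- reference_index(sim$reference)
  calls <- classify_transfrags(sim$transfrags, idx)
  tf_cpm <- .transfrag_cpm(sim$transfrags)
  accepted <- accept_novel_isoforms(calls, sim$transfrags, tf_cpm,
                                    min_support = th$min_support,
                                    min_isoform_fraction =
                                      th$min_isoform_fraction,
                                    min_cpm = th$min_cpm)
  novel <- call_novel_genes(calls, sim$transfrags,
                            min_support = th$min_support)
  improved <- build_improved_annotation(sim$reference, sim$transfrags,
                                        calls, accepted,
                                        min_support = th$min_support)
  ext <- measure_extensions(improved, sim$reference)
  timings["compare"] <- tic() - t0

  # --- orfs ----------------------------------------------------------
  t0 <- tic()
  orf_report <- cds_improvement_report(sim$reference, improved,
                                       sim$genome, min_aa = th$min_aa)
  timings["orfs"] <- tic() - t0

  # --- rescue --------------------------------------------------------
  t0 <- tic()
  retained_reads <- rescue_filter_reads(sim$unmapped_reads)
  rep_lib <- .repeat_library(sim$repeats$features, sim$genome)
  rescued <- rescue_pipeline(sim$contigs, repeat_library = rep_lib,
                             min_tpm = th$min_tpm,
                             min_reads = th$min_reads,
                             identity = th$identity, min_aa = th$min_aa)
  timings["rescue"] <- tic() - t0

  # --- repeats -------------------------------------------------------
  t0 <- tic()
  merged <- merge_repeat_features(sim$repeats$features)
  regions <- filter_regions_by_length(merged, th$min_region_bp)
  rq <- assign_pairs_fractional(sim$repeats$alignments, improved, regions)
  timings["repeats"] <- tic() - t0

  # --- de ------------------------------------------------------------
  t0 <- tic()
  gene_of_tx <- setNames(model_genes(sim$truth), model_ids(sim$truth))
  gcounts <- rowsum(sim$counts, gene_of_tx[rownames(sim$counts)])
  norm <- cpm_tpm(gcounts)
  keep <- filter_low_expression(norm$cpm, th$min_cpm, 2)
  expressed <- count_expressed_genes(gcounts, sim$meta,
                                     th$expressed_cutoff)
  fcounts <- gcounts[keep, , drop = FALSE]
  factors <- tmm_factors(fcounts)
  de <- nb_wald_test(fcounts, sim$meta, factors)
  de <- classify_degs(de, th$fc, th$padj)
  top_up <- top_k_table(de, norm$cpm, sim$meta, "up", th$top_k)
  top_down <- top_k_table(de, norm$cpm, sim$meta, "down", th$top_k)
  timings["de"] <- tic() - t0

  # --- enrich --------------------------------------------------------
  t0 <- tic()
  planted <- sim$ledger$planted_de
  if (is.null(term_map))
    term_map <- .make_term_map(keep,
                               intersect(planted$gene_id[
                                 planted$direction == "up"], keep),
                               intersect(planted$gene_id[
                                 planted$direction == "down"], keep),
                               config$seed)
  up_genes <- de$gene_id[de$label == "up"]
  enr <- hypergeom_enrichment(up_genes, keep, term_map, th$enrich_fdr)
  timings["enrich"] <- tic() - t0

  report <- list(
    seed = config$seed,
    thresholds = th,
    transfrags_in = length(sim$transfrags),
    class_codes = as.list(table(calls$code)),
    accepted_isoforms = length(accepted),
    novel_loci = length(unique(novel$locus_id)),
    genes_extended = as.list(table(ext$category)),
    orf_categories = as.list(table(orf_report$category)),
    expressed_genes = lapply(expressed, length),
    reads_retained = length(retained_reads),
    contigs_in = nrow(sim$contigs),
    contigs_retained = nrow(rescued),
    repeat_regions = nrow(regions),
    deg_up = sum(de$label == "up"),
    deg_down = sum(de$label == "down"),
    enriched_terms = sum(enr$enriched))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(sim$genome, p("genome.fa"))
    write_gtf(sim$truth, p("truth.gtf"))
    write_gtf(sim$reference, p("reference.gtf"))
    write_gtf(improved, p("improved.gtf"))
    write_gtf(lapply(sim$transfrags, `[[`, "model"), p("transfrags.gtf"))
    write_count_table(sim$counts, p("transcript_counts.tsv"),
                      "transcript_id")
    write_count_table(gcounts, p("gene_counts.tsv"))
    write_alignments(sim$repeats$alignments, p("repeat_alignments.tsv"))
    write_repeat_gff3(sim$repeats$features, p("repeats.gff3"))
    write_fasta(sim$unmapped_reads, p("unmapped_reads.fa"))
    write_ledger(sim$ledger, p("ledger.json"))
    .write_df(calls, p("class_codes.tsv"))
    .write_df(ext, p("extensions.tsv"))
    .write_df(orf_report, p("orf_report.tsv"))
    .write_df(de, p("de_results.tsv"))
    .write_df(enr, p("enrichment.tsv"))
    jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  structure(list(report = report, timings = timings, sim = sim,
                 calls = calls, accepted_isoforms = accepted,
                 novel_loci = novel, improved = improved,
                 extensions = ext, orf_report = orf_report,
                 retained_reads = retained_reads, rescued = rescued,
                 repeat_regions = regions, repeat_quant = rq,
                 gene_counts = gcounts, cpm = norm$cpm,
                 tested_genes = keep, tmm = factors,
                 de_results = de,
                 top_tables = list(up = top_up, down = top_down),
                 enrichment = enr),
            class = "txforge_run")
}

.write_df <- function(df, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @export
print.txforge_run <- function(x, ...) {
  r <- x$report
  cat("txforge pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  transfrags in            %d\n", r$transfrags_in))
  cat(sprintf("  novel loci               %d\n", r$novel_loci))
  cat(sprintf("  accepted novel isoforms  %d\n", r$accepted_isoforms))
  cat(sprintf("  contigs retained         %d / %d\n", r$contigs_retained,
              r$contigs_in))
  cat(sprintf("  repeat regions > 0.5 kb  %d\n", r$repeat_regions))
  cat(sprintf("  DEGs up / down           %d / %d\n", r$deg_up,
              r$deg_down))
  cat(sprintf("  enriched terms           %d\n", r$enriched_terms))
  invisible(x)
}
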
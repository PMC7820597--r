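test_that("config validation rejects bad probabilities and rates", {
  expect_error(sim_config(p_drop_gene = 1.2), "config error")
  expect_error(sim_config(dispersion = 0), "config error")
  expect_error(sim_config(polyA_fraction = 0.6, lowgc_fraction = 0.6),
               "config error")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_genes = 12, n_contigs = 1,
                    contig_length = 80000)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(write_gtf(a$truth), write_gtf(b$truth))
  expect_identical(write_gtf(a$reference), write_gtf(b$reference))
  expect_identical(a$counts, b$counts)
  expect_identical(a$repeats$alignments, b$repeats$alignments)
  expect_identical(a$unmapped_reads, b$unmapped_reads)
  expect_identical(a$ledger, b$ledger)
})

test_that("genome shape and composition follow the config", {
  cfg <- sim_config(seed = 9, n_contigs = 2, contig_length = 100000,
                    gc = 0.5)
  g <- generate_genome(cfg)
  expect_length(g, 2)
  expect_equal(unique(nchar(g)), 100000)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gte(gc, 0.49)
  expect_lte(gc, 0.51)
  expect_length(generate_genome(sim_config(n_contigs = 0)), 0)
})

test_that("identity and total degradation behave as limits", {
  cfg0 <- sim_config(seed = 5, n_genes = 10, n_contigs = 1,
                     contig_length = 80000, p_drop_gene = 0,
                     p_drop_isoform = 0, p_truncate_5p = 0,
                     p_truncate_3p = 0)
  ann0 <- generate_annotation_pair(generate_genome(cfg0), cfg0)
  expect_identical(write_gtf(ann0$reference), write_gtf(ann0$truth))
  expect_equal(nrow(ann0$ledger$truncations), 0)

  cfg1 <- sim_config(seed = 5, n_genes = 10, n_contigs = 1,
                     contig_length = 80000, p_drop_gene = 1)
  ann1 <- generate_annotation_pair(generate_genome(cfg1), cfg1)
  expect_length(ann1$reference, 0)
  expect_setequal(ann1$ledger$dropped_genes,
                  unique(model_genes(ann1$truth)))
})

test_that("recorded truncations match the emitted annotations", {
  cfg <- sim_config(seed = 13, n_genes = 15, n_contigs = 1,
                    contig_length = 100000, p_drop_gene = 0)
  ann <- generate_annotation_pair(generate_genome(cfg), cfg)
  tr <- ann$ledger$truncations
  expect_gt(nrow(tr), 0)
  truth_by_tx <- setNames(ann$truth, model_ids(ann$truth))
  for (m in ann$reference) {
    t5 <- t3 <- 0
    hit <- tr[tr$gene_id == m$gene_id, ]
    if (nrow(hit)) { t5 <- hit$five_prime_bp; t3 <- hit$three_prime_bp }
    truth <- truth_by_tx[[m$transcript_id]]
    expect_equal(tx_spliced_length(truth) - tx_spliced_length(m), t5 + t3)
    # spliced truncation projects to the same genomic distance
    left <- unname(m$exons[1, 1] - truth$exons[1, 1])
    right <- unname(truth$exons[nrow(truth$exons), 2] -
                      m$exons[nrow(m$exons), 2])
    if (m$strand == "+") {
      expect_equal(left, t5)
      expect_equal(right, t3)
    } else {
      expect_equal(right, t5)
      expect_equal(left, t3)
    }
  }
})

test_that("simulated counts follow the planted NB model", {
  cfg <- sim_config(seed = 17, n_genes = 40, n_contigs = 2,
                    contig_length = 250000, dispersion = 1e-6,
                    mean_log = log(100), sd_log = 0, p_de = 0)
  ann <- generate_annotation_pair(generate_genome(cfg), cfg)
  cnt <- simulate_counts(ann$truth, cfg)$counts
  # near-Poisson limit: mean over >= 160 draws within 3 sd of 100
  n <- length(cnt)
  expect_lt(abs(mean(cnt) - 100), 3 * sqrt(100 / n))

  # planted fold change: ratio of Egg/PVS means within NB sampling bounds
  cfg2 <- sim_config(seed = 18, n_genes = 100, n_contigs = 4,
                     contig_length = 300000, mean_log = log(500),
                     sd_log = 0, p_de = 1, de_log2fc = 2)
  ann2 <- generate_annotation_pair(generate_genome(cfg2), cfg2)
  out2 <- simulate_counts(ann2$truth, cfg2)
  up <- out2$ledger$planted_de$gene_id[out2$ledger$planted_de$direction ==
                                         "up"]
  gid <- model_genes(ann2$truth)
  sel <- gid %in% up
  ratio <- mean(out2$counts[sel, c("Egg_1", "Egg_2")]) /
    mean(out2$counts[sel, c("PVS_1", "PVS_2")])
  expect_gte(ratio, 3.0)
  expect_lte(ratio, 5.3)
})

test_that("transfrag bookkeeping ties support to captured counts", {
  cfg <- sim_config(seed = 19, n_genes = 15, n_contigs = 1,
                    contig_length = 100000, noise_transfrag_rate = 0)
  ann <- generate_annotation_pair(generate_genome(cfg), cfg)
  cnt <- simulate_counts(ann$truth, cfg)
  tfs <- simulate_transfrags(ann$truth, cnt$counts, cfg, cnt$ledger)
  expressed <- rownames(cnt$counts)[rowSums(cnt$counts) > 0]
  src <- vapply(tfs$transfrags, function(t)
    t$model$attributes[["source_tx"]], "")
  expect_setequal(src, expressed)
  for (t in tfs$transfrags) {
    tot <- sum(cnt$counts[t$model$attributes[["source_tx"]], ])
    expect_equal(t$support_pairs, as.integer(round(cfg$capture_rate * tot)))
    expect_equal(unname(t$abundance["PVS"] + t$abundance["Egg"]), tot)
  }
  # noise injection stays below the support threshold and is recorded
  cfgN <- sim_config(seed = 19, n_genes = 15, n_contigs = 1,
                     contig_length = 100000, noise_transfrag_rate = 0.3)
  tfsN <- simulate_transfrags(ann$truth, cnt$counts, cfgN, cnt$ledger)
  noise <- tfsN$ledger$noise_transfrags
  expect_gt(length(noise), 0)
  sup <- vapply(tfsN$transfrags, `[[`, 0, "support_pairs")
  ids <- vapply(tfsN$transfrags, function(t) t$model$transcript_id, "")
  expect_true(all(sup[ids %in% noise] < 20))
})

test_that("unmapped pool partitions into labelled source categories", {
  cfg <- sim_config(seed = 23, n_genes = 20, n_contigs = 1,
                    contig_length = 150000, p_drop_gene = 0.3)
  ann <- generate_annotation_pair(generate_genome(cfg), cfg)
  pool <- simulate_unmapped_pool(ann$truth, ann$ledger, ann$genome, cfg)
  pref <- sub("_.*$", "", names(pool))
  expect_setequal(unique(pref), c("drop", "polyA", "lowgc"))
  n_drop <- sum(pref == "drop")
  expect_equal(n_drop, length(ann$ledger$dropped_genes) *
                 cfg$reads_per_dropped_tx +
                 sum(model_genes(ann$truth) %in% ann$ledger$dropped_genes &
                       grepl("t2$", model_ids(ann$truth))) *
                 cfg$reads_per_dropped_tx)
  # poly-A reads carry a terminal A/T run longer than 4
  pa <- pool[pref == "polyA"]
  expect_true(all(grepl("(A{5,}$)|(^T{5,})|(T{5,}$)", pa)))
  lg <- pool[pref == "lowgc"]
  gc <- vapply(lg, function(s)
    nchar(gsub("[^GC]", "", s)) / nchar(s), 0)
  expect_true(all(gc <= 0.2))

  # no dropped genes and zero junk -> empty pool
  cfg0 <- sim_config(seed = 23, n_genes = 5, n_contigs = 1,
                     contig_length = 60000, p_drop_gene = 0,
                     polyA_fraction = 0, lowgc_fraction = 0)
  ann0 <- generate_annotation_pair(generate_genome(cfg0), cfg0)
  expect_length(simulate_unmapped_pool(ann0$truth, ann0$ledger,
                                       ann0$genome, cfg0), 0)
})

test_that("repeat landscape covers configured classes and clusters", {
  cfg <- sim_config(seed = 29, n_contigs = 2, contig_length = 150000)
  out <- simulate_repeat_landscape(generate_genome(cfg), cfg)
  feats <- out$features
  expect_setequal(unique(feats$repeat_class), cfg$repeat_classes$class)
  expect_equal(as.vector(table(feats$repeat_class)[
    cfg$repeat_classes$class]), cfg$repeat_classes$copies)
  # ledger clusters partition the features
  expect_setequal(unlist(out$ledger$repeat_clusters), feats$feature_id)
  # multi-hit pairs contribute one row per placement
  aln <- out$alignments
  multi <- aln[aln$n_hits > 1, ]
  if (nrow(multi)) {
    tab <- table(paste(multi$pair_id, multi$sample))
    nh <- tapply(multi$n_hits, paste(multi$pair_id, multi$sample), max)
    expect_true(all(tab == nh[names(tab)]))
  }
  # a class with zero copies is absent
  cfg0 <- sim_config(seed = 29, n_contigs = 1, contig_length = 100000,
                     repeat_classes = data.frame(
                       class = c("Tc1-mariner", "Empty"),
                       copies = c(3L, 0L), min_len = 300, max_len = 900))
  out0 <- simulate_repeat_landscape(generate_genome(cfg0), cfg0)
  expect_false("Empty" %in% out0$features$repeat_class)
})

test_that("the truth ledger survives a JSON round trip", {
  cfg <- sim_config(seed = 31, n_genes = 10, n_contigs = 1,
                    contig_length = 80000)
  sim <- simulate_experiment(cfg)
  f <- tempfile(fileext = ".json")
  write_ledger(sim$ledger, f)
  back <- read_ledger(f)
  expect_setequal(back$dropped_genes, sim$ledger$dropped_genes)
  expect_equal(back$truncations$five_prime_bp,
               sim$ledger$truncations$five_prime_bp)
  expect_setequal(back$cds_truncated_5p, sim$ledger$cds_truncated_5p)
})
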
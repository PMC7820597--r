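ref_two_gene <- function() {
  list(
    mk_tx("r1", "gA", list(c(1000, 1200), c(1500, 1700), c(2000, 2300))),
    mk_tx("r2", "gB", list(c(5000, 5400), c(5800, 6100)), strand = "-"))
}

test_that("intron-chain class codes follow their definitions", {
  idx <- reference_index(ref_two_gene())
  # identical junctions, 5' exon extended 300 bp -> "="
  eq <- mk_tx("t_eq", "x", list(c(700, 1200), c(1500, 1700), c(2000, 2300)))
  expect_equal(classify_transfrag(eq, idx)$code, "=")
  expect_equal(classify_transfrag(eq, idx)$matched_reference_transcript,
               "r1")
  # shares junction 1 plus a novel internal junction -> "j"
  j <- mk_tx("t_j", "x", list(c(1000, 1200), c(1500, 1600), c(1650, 2300)))
  cj <- classify_transfrag(j, idx)
  expect_equal(cj$code, "j")
  expect_equal(cj$matched_locus, "gA")
  # contig with no reference features -> "u"
  u <- mk_tx("t_u", "x", list(c(100, 500)), contig = "chrZ")
  expect_equal(classify_transfrag(u, idx)$code, "u")
  # overlap on the opposite strand only -> not "u", not "=": "other"
  anti <- mk_tx("t_anti", "x", list(c(1000, 1300)), strand = "-")
  expect_equal(classify_transfrag(anti, idx)$code, "other")
  # single-exon transfrag inside an intron of r1 -> no exon overlap -> "u"
  intronic <- mk_tx("t_in", "x", list(c(1750, 1950)))
  expect_equal(classify_transfrag(intronic, idx)$code, "u")
})

test_that("classification equals the exhaustive junction-set oracle", {
  set.seed(404)
  for (case in 1:100) {
    n_ref <- sample(1:10, 1)
    refs <- lapply(seq_len(n_ref), function(i)
      rand_model(paste0("r", i), gene = paste0("g", sample(1:4, 1)),
                 origin = sample(1:30000, 1)))
    idx <- reference_index(refs)
    # mix derived and unrelated transfrags
    tf <- if (runif(1) < 0.5) {
      base <- refs[[sample(n_ref, 1)]]
      ex <- base$exons
      mode <- sample(3, 1)
      if (mode == 1 && nrow(ex) > 2) ex <- ex[-2, , drop = FALSE]
      if (mode == 2) ex[1, 1] <- max(0, ex[1, 1] - sample(50:300, 1))
      transcript_model("tf", "tfg", base$contig, base$strand, ex)
    } else rand_model("tf", origin = sample(1:40000, 1))
    got <- classify_transfrag(tf, idx)$code
    expect_equal(got, oracle_classify(tf, refs),
                 info = paste("case", case))
  }
})

test_that("novel isoform acceptance applies all three filters", {
  idx <- reference_index(ref_two_gene())
  jmodel <- mk_tx("tj", "x", list(c(1000, 1200), c(1500, 1600),
                                  c(1650, 2300)))
  eqmodel <- mk_tx("te", "x", list(c(1000, 1200), c(1500, 1700),
                                   c(2000, 2300)))
  mk_set <- function(j_support, j_ab, cpm_j) {
    tfs <- list(mk_transfrag(eqmodel, 100, c(PVS = 100, Egg = 80)),
                mk_transfrag(jmodel, j_support, j_ab))
    calls <- classify_transfrags(tfs, idx)
    cpm <- rbind(te = c(PVS = 50, Egg = 40), tj = cpm_j)
    accept_novel_isoforms(calls, tfs, cpm)
  }
  expect_equal(mk_set(25, c(PVS = 50, Egg = 10), c(PVS = 2, Egg = 0.2)),
               "tj")
  # abundance 39 vs major 100 -> rejected
  expect_length(mk_set(25, c(PVS = 39, Egg = 10), c(PVS = 2, Egg = 2)), 0)
  # CPM 0.9 in both conditions -> rejected
  expect_length(mk_set(25, c(PVS = 50, Egg = 10),
                       c(PVS = 0.9, Egg = 0.9)), 0)
  # support below 20 -> rejected
  expect_length(mk_set(19, c(PVS = 50, Egg = 10), c(PVS = 2, Egg = 2)), 0)
  # boundary: abundance exactly 40% of major passes
  expect_equal(mk_set(20, c(PVS = 40, Egg = 0), c(PVS = 2, Egg = 0)), "tj")
})

test_that("novel gene loci cluster by same-strand exon overlap", {
  idx <- reference_index(ref_two_gene())
  a <- mk_transfrag(mk_tx("ua", "x", list(c(10000, 10500)))) # + strand
  b <- mk_transfrag(mk_tx("ub", "x", list(c(10300, 10900))))
  c_ <- mk_transfrag(mk_tx("uc", "x", list(c(10300, 10900)),
                           strand = "-"))
  d <- mk_transfrag(mk_tx("ud", "x", list(c(20000, 20400))), support = 5L)
  tfs <- list(a, b, c_, d)
  calls <- classify_transfrags(tfs, idx)
  expect_true(all(calls$code == "u"))
  loci <- call_novel_genes(calls, tfs)
  # a+b share a locus; c on the opposite strand is separate; d under-supported
  expect_equal(length(unique(loci$locus_id)), 2)
  expect_equal(sort(loci$transfrag_id[loci$locus_id ==
                                        loci$locus_id[loci$transfrag_id == "ua"]]),
               c("ua", "ub"))
  expect_false("ud" %in% loci$transfrag_id)
  expect_true(all(grepl("^XLOC_", loci$locus_id)))
})

test_that("raising thresholds is monotone in accepted calls", {
  set.seed(405)
  cfg <- sim_config(seed = 15, n_genes = 30, n_contigs = 2,
                    contig_length = 200000, noise_transfrag_rate = 0.2)
  sim <- simulate_experiment(cfg)
  idx <- reference_index(sim$reference)
  calls <- classify_transfrags(sim$transfrags, idx)
  n_loci <- vapply(c(1, 10, 20, 50, 200), function(th)
    length(unique(call_novel_genes(calls, sim$transfrags, th)$locus_id)),
    0L)
  expect_true(all(diff(n_loci) <= 0))
  cpm <- matrix(5, nrow = length(sim$transfrags), ncol = 2,
                dimnames = list(vapply(sim$transfrags, function(t)
                  t$model$transcript_id, ""), c("PVS", "Egg")))
  n_iso <- vapply(c(0.1, 0.4, 0.8, 1.0), function(fr)
    length(accept_novel_isoforms(calls, sim$transfrags, cpm,
                                 min_isoform_fraction = fr)), 0L)
  expect_true(all(diff(n_iso) <= 0))
})

test_that("expressed-gene counting respects the threshold boundary", {
  cnt <- rbind(g1 = c(20, 19, 0, 0), g2 = c(20, 20, 5, 5),
               g3 = c(0, 0, 0, 0))
  colnames(cnt) <- c("PVS_1", "PVS_2", "Egg_1", "Egg_2")
  meta <- data.frame(sample = colnames(cnt),
                     condition = c("PVS", "PVS", "Egg", "Egg"))
  ex40 <- count_expressed_genes(cnt, meta, 40)
  expect_equal(ex40$PVS, "g2")          # 39 excluded, exactly 40 included
  expect_length(ex40$Egg, 0)
  ex10 <- count_expressed_genes(cnt, meta, 10)
  expect_setequal(ex10$PVS, c("g1", "g2"))
  expect_equal(ex10$Egg, "g2")
  empty <- count_expressed_genes(cnt[0, , drop = FALSE], meta, 40)
  expect_length(empty$PVS, 0)
  expect_error(count_expressed_genes(-cnt, meta), "negative")
})

test_that("extensions are strand-aware genomic distances", {
  ref <- list(mk_tx("r1", "g1", list(c(5000, 5400), c(5800, 6100)),
                    strand = "-"))
  imp <- list(mk_tx("r1", "g1", list(c(5000, 5400), c(5800, 8100)),
                    strand = "-"))
  ext <- measure_extensions(imp, ref)
  expect_equal(ext$five_prime_ext_bp, 2000)  # 5' of a minus gene = right end
  expect_equal(ext$three_prime_ext_bp, 0)
  expect_equal(ext$category, "5' only")

  same <- measure_extensions(ref, ref)
  expect_equal(same$five_prime_ext_bp, 0)
  expect_equal(same$category, "none")

  extra <- c(imp, list(mk_tx("n1", "gN", list(c(1, 100)))))
  expect_message(measure_extensions(extra, ref), "skipping")
})

test_that("ledger truncations are recovered as extensions exactly", {
  cfg <- sim_config(seed = 21, n_genes = 40, n_contigs = 2,
                    contig_length = 250000, noise_transfrag_rate = 0)
  sim <- simulate_experiment(cfg)
  idx <- reference_index(sim$reference)
  calls <- classify_transfrags(sim$transfrags, idx)
  imp <- build_improved_annotation(sim$reference, sim$transfrags, calls)
  ext <- measure_extensions(imp, sim$reference)
  tr <- sim$ledger$truncations
  mer <- merge(ext, tr, by = "gene_id", all = TRUE)
  mer[is.na(mer)] <- 0
  expect_equal(mer$five_prime_ext_bp, mer$five_prime_bp)
  expect_equal(mer$three_prime_ext_bp, mer$three_prime_bp)
  # every transfrag got exactly one code
  expect_true(all(calls$code %in% c("=", "j", "u", "other")))
  expect_equal(nrow(calls), length(sim$transfrags))
})
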
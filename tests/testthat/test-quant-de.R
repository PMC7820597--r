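de_meta <- data.frame(sample = c("PVS_1", "PVS_2", "Egg_1", "Egg_2"),
                      condition = c("PVS", "PVS", "Egg", "Egg"),
                      replicate = c(1L, 2L, 1L, 2L),
                      stringsAsFactors = FALSE)

test_that("pair counting applies flags, uniqueness and largest overlap", {
  ann <- list(mk_tx("tA", "gA", list(c(1000, 2000)), contig = "c1"),
              mk_tx("tB", "gB", list(c(1950, 3000)), contig = "c1"))
  aln <- data.frame(
    pair_id = c("p_largest", "p_diffctg", "p_multi", "p_multi", "p_multi",
                "p_tie"),
    sample = "PVS_1", contig = "c1", strand = "+",
    blocks = c("1870-1950;1960-2040",   # 80 bases in gA, 70+20 in gB
               "1000-1100;1200-1300",
               "1000-1100;1200-1300", "1010-1110;1210-1310",
               "1020-1120;1220-1320",
               "1940-1950;2000-2010"),  # 10 bases each -> tie
    n_hits = c(1L, 1L, 3L, 3L, 3L, 1L),
    both_ends_aligned = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    same_contig_strand = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  out <- count_gene_pairs(aln, ann)
  # p_largest: gA overlaps 80+40 = 120 bases, gB 80 -> counted for gA only;
  # p_tie: 10 bases each -> both genes counted under -O semantics
  expect_equal(out$stats$excluded, 1)        # different-contig pair
  expect_equal(out$stats$multi_excluded, 1)  # n_hits = 3
  expect_equal(unname(out$counts["gA", "PVS_1"]), 2)
  expect_equal(unname(out$counts["gB", "PVS_1"]), 1)
  strict <- count_gene_pairs(aln, ann, tie_policy = "strict")
  expect_equal(sum(strict$counts), 1)  # only the tie pair is dropped

  clear <- data.frame(
    pair_id = "p1", sample = "PVS_1", contig = "c1", strand = "+",
    blocks = "1100-1180;1900-1980", n_hits = 1L,
    both_ends_aligned = TRUE, same_contig_strand = TRUE,
    stringsAsFactors = FALSE)
  out2 <- count_gene_pairs(clear, ann)
  # gA overlap 80 + 50, gB overlap 30 -> gA only
  expect_equal(out2$counts["gA", "PVS_1"], 1)
  expect_equal(out2$counts["gB", "PVS_1"], 0)
  expect_error(count_gene_pairs(transform(clear, contig = "cX"), ann),
               "integrity error")
})

test_that("CPM and TPM match their definitions", {
  cnt <- matrix(c(50, 50, 50, 50, 100, 100, 100, 100), nrow = 4,
                dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  out <- cpm_tpm(cnt, lengths = setNames(rep(1000, 4), paste0("g", 1:4)),
                 library_size = c(s1 = 1e6, s2 = 2e6))
  expect_equal(out$cpm["g1", "s1"], 50)
  expect_equal(unique(as.vector(out$tpm)), 250000)
  expect_equal(colSums(out$tpm), c(s1 = 1e6, s2 = 1e6))
  expect_error(cpm_tpm(cnt, library_size = c(0, 1)), "zero library")
})

test_that("low-expression filter is strict in CPM and sample count", {
  cpm <- rbind(keep = c(1.5, 1.2, 0, 0),
               boundary = c(1.0, 1.0, 1.0, 1.0),
               one_sample = c(5, 0.5, 0.5, 0.5))
  colnames(cpm) <- de_meta$sample
  expect_equal(filter_low_expression(cpm), "keep")
  expect_length(filter_low_expression(cpm[0, , drop = FALSE]), 0)
})

test_that("TMM factors satisfy identity/depth cases and match edgeR", {
  set.seed(606)
  cnt <- matrix(rnbinom(2000, mu = 200, size = 10), ncol = 4,
                dimnames = list(NULL, de_meta$sample))
  same <- cbind(cnt[, 1], cnt[, 1])
  colnames(same) <- c("a", "b")
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  doubled <- cbind(a = cnt[, 1], b = 2L * cnt[, 1])
  f <- tmm_factors(doubled)
  expect_equal(unname(f["b"] / f["a"]), 1, tolerance = 1e-9)

  skip_if_not_installed("edgeR")
  ef <- edgeR::calcNormFactors(cnt, method = "TMM")
  expect_equal(unname(tmm_factors(cnt)), unname(ef), tolerance = 1e-6)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))),
               "all zeros")
})

test_that("the NB Wald test recovers planted effects and stays calibrated", {
  set.seed(607)
  n <- 600
  mu <- exp(rnorm(n, log(300), 1))
  cnt <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 10))
  rownames(cnt) <- paste0("g", 1:n)
  colnames(cnt) <- de_meta$sample
  de <- nb_wald_test(cnt, de_meta)
  expect_true(all(de$padj >= de$p_value - 1e-12))
  expect_true(all(de$padj <= 1))
  expect_lt(mean(de$p_value < 0.05), 0.1)

  # swapping group labels negates every log2fc exactly
  swapped <- de_meta
  swapped$condition <- c("Egg", "Egg", "PVS", "PVS")
  de_sw <- nb_wald_test(cnt, swapped)
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-8)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-8)

  expect_error(nb_wald_test(cnt[, 1:3],
                            de_meta[1:3, ]), "design error")
})

test_that("DEG labels follow the padj and linear fold-change thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(log2(3), log2(2), log2(10), -log2(4)),
                    padj = c(0.005, 0.005, 0.02, 0.001))
  lab <- classify_degs(res)
  expect_equal(lab$label, c("up", "ns", "ns", "down"))
  # log-scale mode thresholds |log2fc| instead
  lab2 <- classify_degs(res, fc_threshold = 2.5, log_scale = TRUE)
  expect_equal(lab2$label, c("ns", "ns", "ns", "ns"))
})

test_that("top-k tables rank by mean CPM with exclusions", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(3, 3, 3), padj = c(1e-4, 1e-4, 1e-4),
                    label = "up", stringsAsFactors = FALSE)
  cpm <- matrix(c(0, 0, 0, 0, 100, 100, 50, 50, 200, 200, 10, 10),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), de_meta$sample))
  # direction "up" ranks by Egg-sample CPM: a=0, b=50, c=10
  top <- top_k_table(res, cpm, de_meta, "up", k = 2)
  expect_equal(top$gene_id, c("b", "c"))
  top2 <- top_k_table(res, cpm, de_meta, "up", k = 2, exclude = "b")
  expect_equal(top2$gene_id, c("c", "a"))
  expect_equal(nrow(top_k_table(res[1, ], cpm, de_meta, "up", k = 25)), 1)
  expect_error(top_k_table(res, cpm, de_meta, "up", k = 0),
               "argument error")
})

test_that("hypergeometric enrichment matches closed forms", {
  bg <- paste0("g", 1:1000)
  term <- paste0("g", 1:10)
  out <- hypergeom_enrichment(term, bg, list(T1 = term))
  expect_equal(out$p_value, 1 / choose(1000, 10))
  expect_true(out$enriched)
  expect_equal(out$enrichment_ratio, (10 / 10) / (10 / 1000))

  # zero overlap -> untested; overlap present but random -> p near 1 case
  out2 <- hypergeom_enrichment(paste0("g", 500:600), bg,
                               list(none = paste0("g", 1:10),
                                    all = bg))
  expect_false("none" %in% out2$term)
  expect_equal(out2$p_value[out2$term == "all"], 1)
  expect_error(hypergeom_enrichment("zz", bg, list(T1 = term)),
               "integrity error")
})

test_that("random selections are not spuriously enriched", {
  set.seed(608)
  bg <- paste0("g", 1:500)
  tm <- lapply(1:40, function(i) sample(bg, 25))
  names(tm) <- paste0("T", 1:40)
  frac <- replicate(20, {
    sel <- sample(bg, 50)
    out <- hypergeom_enrichment(sel, bg, tm)
    sum(out$enriched) / 40
  })
  expect_lte(mean(frac), 0.05)
})
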
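test_that("read rescue trims tails and applies strict length/GC gates", {
  set.seed(501)
  # 30 nt ending in 6 A: tail removed, 24 nt left -> discarded (<= 25)
  r1 <- paste0(rand_dna(24, gc = 0.5), "AAAAAA")
  expect_length(rescue_filter_reads(c(a = r1)), 0)
  # tail of exactly 4 A is kept (rule is > 4)
  r2 <- paste0(rand_dna(30, gc = 0.5), "AAAA")
  out2 <- rescue_filter_reads(c(b = r2))
  expect_equal(unname(out2), r2)
  # 50 nt at GC 0.18 -> discarded
  r3 <- paste0(strrep("AT", 20), "GCGCGCGCA")
  expect_lt(nchar(gsub("[^GC]", "", r3)) / nchar(r3), 0.2)
  expect_length(rescue_filter_reads(c(c = r3)), 0)
  # leading T tail is trimmed too
  r4 <- paste0("TTTTTT", rand_dna(60, gc = 0.5))
  out4 <- rescue_filter_reads(c(d = r4))
  expect_equal(unname(nchar(out4)), 60)
  expect_length(rescue_filter_reads(character(0)), 0)
})

test_that("abundance filters use the printed strict boundaries", {
  df <- data.frame(contig_id = c("a", "b", "c"), tpm = c(9.99, 10, 50),
                   estimated_reads = c(100, 19.5, 20),
                   stringsAsFactors = FALSE)
  expect_equal(filter_contigs_by_tpm(df)$contig_id, c("b", "c"))
  expect_equal(filter_contigs_by_reads(df)$contig_id, c("a", "c"))
  expect_error(filter_contigs_by_tpm(df[, 1, drop = FALSE]),
               "integrity error")
})

test_that("greedy clustering groups by identity over the shorter sequence", {
  set.seed(502)
  s <- rand_dna(400)
  # exact duplicates fall into one cluster
  dup <- data.frame(contig_id = c("x", "y"), sequence = c(s, s),
                    estimated_reads = c(10, 5), stringsAsFactors = FALSE)
  cl <- greedy_cluster(dup)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(cl$cluster, c("x", "x"))  # same length: id-order tie-break
  expect_equal(collapse_clusters(cl)$estimated_reads, 15)

  # 10 mismatches over a 100 nt sequence: identity 0.90 -> separate
  a <- rand_dna(100)
  b <- a
  pos <- seq(5, 95, by = 10)
  for (p in pos) {
    old <- substring(b, p, p)
    substring(b, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  two <- data.frame(contig_id = c("a", "b"), sequence = c(a, b),
                    stringsAsFactors = FALSE)
  expect_equal(length(unique(greedy_cluster(two, 0.95)$cluster)), 2)
  expect_equal(length(unique(greedy_cluster(two, 0.90)$cluster)), 1)

  # reverse-complement duplicates are recognized
  rcdup <- data.frame(contig_id = c("f", "r"), sequence = c(s, revcomp(s)),
                      stringsAsFactors = FALSE)
  expect_equal(length(unique(greedy_cluster(rcdup)$cluster)), 1)
})

test_that("cluster membership is invariant to input order", {
  set.seed(503)
  base <- vapply(1:40, function(i) rand_dna(sample(150:400, 1)), "")
  seqs <- c(base, vapply(sample(base, 15), function(s)
    substring(s, 1, round(nchar(s) * 0.95)), ""))
  df <- data.frame(contig_id = sprintf("c%03d", seq_along(seqs)),
                   sequence = seqs, stringsAsFactors = FALSE)
  cl1 <- greedy_cluster(df)
  perm <- df[sample(nrow(df)), , drop = FALSE]
  cl2 <- greedy_cluster(perm)
  part <- function(cl) {
    groups <- split(cl$contig_id, cl$cluster)
    sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
  }
  expect_identical(unname(part(cl1)), unname(part(cl2)))
})

test_that("coding classification uses ORFs and optional protein evidence", {
  set.seed(504)
  coding <- paste0(rand_dna(50), "ATG", strrep("GCT", 150), "TAA",
                   rand_dna(50))
  out <- classify_contig_coding(coding)
  expect_true(out$coding)
  expect_equal(out$completeness, "complete")

  # stop-rich random 400 nt: no >= 100 aa ORF in any frame
  stopish <- paste(replicate(45, paste0(rand_dna(6), "TAA")), collapse = "")
  out2 <- classify_contig_coding(stopish)
  expect_false(out2$coding)

  # protein homology rescues a contig without a long ORF
  pep <- paste(sample(c("M", "A", "L", "K", "D", "E", "F", "G"), 80,
                      replace = TRUE), collapse = "")
  codon_of <- c(M = "ATG", A = "GCT", L = "CTT", K = "AAA", D = "GAT",
                E = "GAA", F = "TTT", G = "GGT")
  dna <- paste(codon_of[strsplit(pep, "")[[1]]], collapse = "")
  dna <- paste0(dna, "TAA", rand_dna(30))
  out3 <- classify_contig_coding(dna, protein_set = c(p1 = pep),
                                 min_aa = 100)
  expect_true(out3$coding)
})

test_that("repeat novelty calls depend on identity and coverage", {
  set.seed(505)
  lib <- c(consA = rand_dna(800), consB = rand_dna(600))
  expect_equal(repeat_novelty_call(lib[["consA"]], lib), "known")
  # contig sharing only a 30% high-identity segment -> novel (low coverage)
  partial <- paste0(substring(lib[["consA"]], 1, 150), rand_dna(350))
  expect_equal(repeat_novelty_call(partial, lib), "novel")
  expect_equal(repeat_novelty_call(rand_dna(500), lib), "no_hit")
  expect_warning(out <- repeat_novelty_call(rand_dna(100), character(0)),
                 "empty")
  expect_equal(out, "no_hit")
})

test_that("the filter cascade is idempotent and keeps planted signal", {
  cfg <- sim_config(seed = 33, n_genes = 25, n_contigs = 2,
                    contig_length = 150000, p_drop_gene = 0.2)
  sim <- simulate_experiment(cfg)
  res <- rescue_pipeline(sim$contigs)
  # survivors from dropped genes are coding; junk never survives
  expect_true(all(res$coding[res$source != "junk"]))
  expect_false(any(res$source == "junk"))
  # rerun on its own output: nothing changes but re-clustering metadata
  res2 <- rescue_pipeline(res[, c("contig_id", "stage", "sequence", "tpm",
                                  "estimated_reads", "source")])
  expect_setequal(res2$contig_id, res$contig_id)
  expect_equal(res2$estimated_reads[order(res2$contig_id)],
               res$estimated_reads[order(res$contig_id)])
  # every input contig of the dedup step lands in exactly one cluster
  cl <- greedy_cluster(sim$contigs)
  expect_equal(nrow(cl), nrow(sim$contigs))
  expect_false(any(is.na(cl$cluster)))
})

test_that("quality gate drops externally failed contigs", {
  cfg <- sim_config(seed = 34, n_genes = 15, n_contigs = 1,
                    contig_length = 100000, p_drop_gene = 0.3)
  sim <- simulate_experiment(cfg)
  base <- rescue_pipeline(sim$contigs)
  qs <- data.frame(contig_id = base$contig_id[1], pass = FALSE,
                   stringsAsFactors = FALSE)
  gated <- rescue_pipeline(sim$contigs, quality_scores = qs)
  expect_false(base$contig_id[1] %in% gated$contig_id)
})
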
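ranked_fixture <- function(p) {
  su <- data.frame(gene_symbol = names(p), chasm_gene_p = unname(p),
                   stringsAsFactors = FALSE)
  rank_genes(su)
}

test_that("gene ranking is by -log10 p with lexicographic tie-breaks", {
  r <- ranked_fixture(c(B = 0.1, A = 0.01))
  expect_identical(r$gene_symbol, c("A", "B"))
  expect_equal(r$score, c(2, 1))

  tied <- ranked_fixture(c(ZED = 0.05, ABLE = 0.05, MID = 0.01))
  expect_identical(tied$gene_symbol, c("MID", "ABLE", "ZED"))

  set.seed(6)
  p <- setNames(runif(30), sprintf("G%02d", 1:30))
  r1 <- ranked_fixture(p)
  r2 <- ranked_fixture(sample(p))
  expect_identical(r1, r2)
})

test_that("enrichment score matches the brute-force running sum everywhere", {
  set.seed(7)
  for (i in 1:60) {
    N <- sample(4:12, 1)
    m <- sample(1:(N - 1), 1)
    scores <- sort(round(runif(N, 0, 3), 2), decreasing = TRUE)
    ranked <- data.frame(gene_symbol = sprintf("g%02d", 1:N), score = scores,
                         stringsAsFactors = FALSE)
    members <- sample(ranked$gene_symbol, m)
    wexp <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(ranked, members, wexp)
    oracle <- es_bruteforce(scores, ranked$gene_symbol %in% members, wexp)
    expect_equal(es$es, oracle, tolerance = 1e-12)
    expect_length(es$running, N)
  }
})

test_that("a top-of-list set scores positive, a bottom set negative", {
  ranked <- data.frame(gene_symbol = sprintf("g%02d", 1:10),
                       score = rep(1, 10), stringsAsFactors = FALSE)
  top <- enrichment_score(ranked, ranked$gene_symbol[1:3], 0)
  expect_gt(top$es, 0)
  expect_setequal(top$leading_edge, ranked$gene_symbol[1:3])
  bottom <- enrichment_score(ranked, ranked$gene_symbol[6:10], 0)
  expect_lt(bottom$es, 0)
  expect_error(enrichment_score(ranked, "absent"), "no overlap")
})

test_that("enrichment score agrees with an external GSEA statistic", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  for (i in 1:10) {
    N <- 50
    ranked <- data.frame(gene_symbol = sprintf("g%02d", 1:N),
                         score = sort(runif(N, 0.01, 5), decreasing = TRUE),
                         stringsAsFactors = FALSE)
    members <- sample(ranked$gene_symbol, 8)
    es <- enrichment_score(ranked, members, weight_exponent = 1)$es
    stats <- setNames(ranked$score, ranked$gene_symbol)
    ext <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% members),
                               gseaParam = 1, scoreType = "std")
    expect_equal(es, ext, tolerance = 1e-6)
  }
})

test_that("preranked GSEA is reproducible and bounded away from zero p", {
  set.seed(9)
  ranked <- data.frame(gene_symbol = sprintf("g%03d", 1:100),
                       score = sort(rexp(100), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  sets <- list(TOP = ranked$gene_symbol[1:10],
               RAND = sample(ranked$gene_symbol, 15))
  r1 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 42)
  r2 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$p_perm >= 1 / 201))
  expect_true(all(r1$p_perm <= 1))
  expect_lt(r1$p_perm[r1$set_name == "TOP"], 0.05)
  expect_error(gsea_preranked(ranked, list(ALL = ranked$gene_symbol), 200, 1),
               "as large as")
  expect_error(gsea_preranked(ranked, sets, n_perm = 50), "at least 100")
})

test_that("|NES| is centered near 1 for null sets", {
  set.seed(10)
  ranked <- data.frame(gene_symbol = sprintf("g%03d", 1:150),
                       score = sort(runif(150), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  sets <- setNames(lapply(1:150, function(i) sample(ranked$gene_symbol, 12)),
                   sprintf("S%03d", 1:150))
  res <- gsea_preranked(ranked, sets, n_perm = 100, seed = 5)
  expect_lt(abs(mean(abs(res$nes)) - 1), 0.1)
})

test_that("pathway carrier summary reports published-style frequencies", {
  pathway <- sprintf("FA%02d", 1:13)
  # 14 carrier samples, 20 pathway mutations in 13 genes; samples 1 and 2
  # carry two mutated genes each, sample 3 two mutations of one gene
  genes <- c(pathway,                          # 13 muts, samples T01..T13
             pathway[2], pathway[3],           # second gene for T01 and T02
             pathway[3],                       # second hit of T03's own gene
             pathway[5], pathway[6], pathway[7], pathway[8])  # T14 x4
  samples <- c(sprintf("T%02d", 1:13), "T01", "T02", "T03",
               "T14", "T14", "T14", "T14")
  v <- do.call(rbind, lapply(seq_along(genes), function(i)
    make_variant(sample_id = samples[i], pos = 100L + i,
                 gene_symbol = genes[i])))
  s <- pathway_carrier_summary(v, pathway, n_samples = 99)
  expect_identical(s$n_carriers, 14L)
  expect_equal(s$frequency_pct, 14.1)
  expect_identical(s$n_mutations, 20L)

  # one sample with two mutated pathway genes is not exclusive
  v2 <- rbind(make_variant(gene_symbol = "FA01", pos = 1L),
              make_variant(gene_symbol = "FA02", pos = 2L))
  expect_equal(pathway_carrier_summary(v2, pathway, 10)$exclusivity_fraction, 0)

  none <- pathway_carrier_summary(v2, c("OTHER"), 10)
  expect_identical(none$n_carriers, 0L)
})
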
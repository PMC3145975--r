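make_expr <- function(n = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n * 4, mean = 6), nrow = n,
              dimnames = list(sprintf("G%03d", 1:n), c("MK", "CD4", "CD8", "EB")))
  m
}

test_that("gene ranking is deterministic and invariant to input row order", {
  m <- make_expr()
  r1 <- rank_genes(m, "MK")
  r2 <- rank_genes(m[sample(nrow(m)), ], "MK")
  expect_identical(r1, r2)
  expect_true(all(diff(r1$score) <= 0))
  expect_error(rank_genes(m - 100, "MK", pseudocount = 0), "pseudocount")
  expect_error(rank_genes(m, "NK"), "unknown cell type")
})

test_that("a single top-ranked gene with p = 0 attains ES = 1 and the sum returns to 0", {
  ranked <- structure(data.frame(gene_id = letters[1:10], score = 10:1),
                      class = c("RankedGenes", "data.frame"))
  r <- enrichment_score(ranked, "a", weight_p = 0)
  expect_equal(r$es, 1)
  expect_equal(r$running_sum[1], 1)
  expect_equal(r$running_sum[10], 0)
})

test_that("ES matches a hand-enumerated 5-gene running sum", {
  ranked <- structure(data.frame(gene_id = c("a", "b", "c", "d", "e"),
                                 score = c(4, 3, 2, 1, 0.5)),
                      class = c("RankedGenes", "data.frame"))
  # set {a, d}: weighted increments 4/5 and 1/5, decrements 1/3 at b, c, e
  r <- enrichment_score(ranked, c("a", "d"), weight_p = 1)
  manual <- cumsum(c(4 / 5, -1 / 3, -1 / 3, 1 / 5, -1 / 3))
  expect_equal(r$running_sum, manual)
  expect_equal(r$es, manual[which.max(abs(manual))])
})

test_that("ES equals the brute-force oracle on many random small cases and stays in [-1, 1]", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    scores <- sort(round(rnorm(n, sd = 2), 3), decreasing = TRUE)
    ranked <- structure(data.frame(gene_id = sprintf("g%02d", 1:n), score = scores),
                        class = c("RankedGenes", "data.frame"))
    sz <- sample(1:(n - 1), 1)
    set <- sample(ranked$gene_id, sz)
    p <- sample(c(0, 1), 1)
    r <- enrichment_score(ranked, set, weight_p = p)
    expect_equal(r$es, oracle_es(scores, ranked$gene_id %in% set, p))
    expect_true(abs(r$es) <= 1 + 1e-12)
    expect_equal(r$running_sum[n], 0, tolerance = 1e-12)
  }
})

test_that("ES agrees with fgsea's statistic on random cases", {
  set.seed(78)
  for (i in 1:20) {
    n <- 40
    scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranked <- structure(data.frame(gene_id = sprintf("g%02d", 1:n), score = scores),
                        class = c("RankedGenes", "data.frame"))
    set <- sample(ranked$gene_id, 8)
    ours <- enrichment_score(ranked, set, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(scores, ranked$gene_id),
                               which(ranked$gene_id %in% set), gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("degenerate gene sets are rejected", {
  ranked <- structure(data.frame(gene_id = letters[1:5], score = 5:1),
                      class = c("RankedGenes", "data.frame"))
  expect_error(enrichment_score(ranked, "zz"), "no overlap")
  expect_error(enrichment_score(ranked, letters[1:5]), "whole ranked list")
})

test_that("significance is seed-deterministic and a random set is not called significant", {
  m <- make_expr(n = 120, seed = 5)
  ranked <- rank_genes(m, "MK")
  sets <- list(random1 = sample(rownames(m), 15),
               random2 = sample(rownames(m), 10))
  g1 <- gsea_significance(ranked, sets, permutations = 200, seed = 3)
  g2 <- gsea_significance(ranked, sets, permutations = 200, seed = 3)
  expect_identical(g1$fdr_q, g2$fdr_q)
  expect_true(all(abs(g1$nes) < 2.5))
  expect_true(all(g1$p > 0.01))
})

test_that("the planted target list attains the top NES among the 31 pattern lists", {
  cfg <- make_small_config(81)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  he <- generate_histone_and_expression(cfg, genes)
  occ <- assign_patterns(land$peaksets)
  lists <- build_target_gene_lists(occ, genes)
  ranked <- rank_genes(he$expression, "MK")
  g <- suppressWarnings(gsea_significance(ranked, lists, permutations = 200, seed = 9))
  expect_equal(g$set[which.max(abs(g$nes))], "GATA1+GATA2+RUNX1+FLI1+SCL")
  expect_lt(g$fdr_q[which.max(abs(g$nes))], 0.25)
})
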
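test_that("rank_statistic follows the signed log10 formula", {
  expect_equal(rank_statistic(2, 0.01), 2)
  expect_equal(rank_statistic(-1, 0.001), -3)
  expect_equal(rank_statistic(5, 1), 0)
  expect_equal(rank_statistic(0, 0.001), 0)  # sign(0) = 0
  expect_error(rank_statistic(1, 0), "\\(0, 1\\]")
  expect_error(rank_statistic(1, 1.5), "\\(0, 1\\]")
  # antisymmetric under fold-change sign flip
  set.seed(2)
  lfc <- stats::rnorm(50); p <- stats::runif(50)
  expect_equal(rank_statistic(-lfc, p), -rank_statistic(lfc, p))
})

test_that("build_ranked_list orders by statistic with lexicographic ties", {
  tab <- de_table(c("gU", "gZ", "gD"), log2fc = c(1, 0, -1),
                  p = c(0.001, 0.5, 0.001))
  rl <- build_ranked_list(tab)
  expect_equal(rl$gene, c("gU", "gZ", "gD"))
  expect_equal(rl$score, c(3, 0, -3))

  tied <- de_table(c("b", "a"), log2fc = c(1, 1), p = c(0.1, 0.1))
  expect_equal(build_ranked_list(tied)$gene, c("a", "b"))

  dup <- data.frame(gene = c("a", "a"), log2fc = c(1, 2), p = c(0.1, 0.2))
  expect_error(build_ranked_list(dup), "duplicate")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.02, 0.02, 0.02)), c(0.02, 0.02, 0.02))
  # hand step-up: sorted (0.005, 0.01, 0.03, 0.04) * 4/(1..4) then cummin
  # from the top gives (0.02, 0.02, 0.04, 0.04), mapped back to input order
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  # permutation invariance and domination of raw p
  set.seed(4)
  p <- stats::runif(100)
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("deg_filter applies strict thresholds in both and one-sided modes", {
  tab <- de_table(paste0("g", 1:6),
                  log2fc = c(2, -3, 4, 0.5, 2, 1.2),
                  p = c(0.01, 0.02, 0.2, 0.01, 0.5, 0.03),
                  adj_p = c(0.01, 0.02, 0.2, 0.01, 0.5, 0.03))
  expect_equal(deg_filter(tab), c("g1", "g2", "g6"))
  expect_equal(deg_filter(tab, direction = "up"), c("g1", "g6"))
  expect_equal(deg_filter(tab, direction = "down"), "g2")

  # boundaries are strict: log2fc == 1 and adj_p == 0.05 are excluded
  edge <- de_table(c("in", "lfc_at", "p_at"),
                   log2fc = c(1.5, 1.0, 1.5),
                   p = c(0.04, 0.04, 0.05),
                   adj_p = c(0.04, 0.04, 0.05))
  expect_equal(deg_filter(edge), "in")

  noadj <- de_table("g1", 2, 0.01)
  expect_error(deg_filter(noadj), "bh_adjust")
})

test_that("gsea_es handles canonical and degenerate cases", {
  rl <- structure(data.frame(gene = paste0("g", 1:10), score = 10:1),
                  class = c("ranked_list", "data.frame"))
  # a single member ranked first peaks immediately at 1
  expect_equal(gsea_es(rl, gene_set("s", "g1"))$es, 1)
  # whole-universe set: decrement undefined
  expect_error(gsea_es(rl, gene_set("all", paste0("g", 1:10))), "N - K = 0")
  # no overlap: explicit empty result, not an error
  none <- gsea_es(rl, gene_set("none", "absent"))
  expect_identical(none$overlap, 0L)
  expect_true(is.na(none$es))

  # top-3 set against the brute-force oracle
  s3 <- gene_set("top", c("g1", "g2", "g3"))
  expect_equal(gsea_es(rl, s3)$es, oracle_es(rl$gene, rl$score, s3$members))
  expect_equal(gsea_es(rl, s3)$leading_edge, c("g1", "g2", "g3"))
})

test_that("gsea_es matches the brute-force oracle and fgsea on random instances", {
  set.seed(31)
  for (i in 1:25) {
    N <- sample(8:40, 1)
    genes <- paste0("g", seq_len(N))
    scores <- sort(stats::rnorm(N), decreasing = TRUE)
    rl <- structure(data.frame(gene = genes, score = scores),
                    class = c("ranked_list", "data.frame"))
    members <- sample(genes, sample(2:min(6, N - 1), 1))
    es <- gsea_es(rl, gene_set("s", members))$es
    expect_equal(es, oracle_es(genes, scores, members))
    # independent reference implementation (weight 1 running sum)
    ref <- fgsea::calcGseaStat(stats::setNames(scores, genes),
                               which(genes %in% members), gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-12)
  }
})

test_that("the O(K) position-based ES equals the full running sum", {
  set.seed(17)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    scores <- sort(stats::rnorm(N), decreasing = TRUE)
    genes <- paste0("g", seq_len(N))
    rl <- structure(data.frame(gene = genes, score = scores),
                    class = c("ranked_list", "data.frame"))
    K <- sample(1:min(10, N - 1), 1)
    pos <- sort(sample.int(N, K))
    full <- gsea_es(rl, gene_set("s", genes[pos]))$es
    fast <- andronet:::es_from_positions(pos, abs(scores[pos]), N)
    expect_equal(fast, full)
  }
})

test_that("gsea_permutation is seed-deterministic and detects a planted top set", {
  set.seed(8)
  n <- 1000
  genes <- paste0("g", 1:n)
  scores <- sort(stats::rnorm(n), decreasing = TRUE)
  rl <- structure(data.frame(gene = genes, score = scores),
                  class = c("ranked_list", "data.frame"))
  top <- gene_set("top", genes[1:25])
  a <- gsea_permutation(rl, top, n_perm = 1000, seed = 5)
  b <- gsea_permutation(rl, top, n_perm = 1000, seed = 5)
  expect_identical(a, b)
  expect_lte(a$p_perm, 0.01)
  expect_gt(a$es, 0)
  expect_gt(a$nes, 1)
  expect_error(gsea_permutation(rl, top, n_perm = 5), "at least 10")
  expect_error(gsea_permutation(rl, gene_set("none", "absent"), n_perm = 100),
               "no members")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(12)
  n <- 300
  genes <- paste0("g", seq_len(n))
  scores <- sort(stats::rnorm(n), decreasing = TRUE)
  rl <- structure(data.frame(gene = genes, score = scores),
                  class = c("ranked_list", "data.frame"))
  ps <- vapply(1:200, function(i) {
    s <- gene_set("r", sample(genes, 10))
    gsea_permutation(rl, s, n_perm = 199, seed = 1000 + i)$p_perm
  }, numeric(1))
  frac <- mean(ps <= 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
})

test_that("hypergeometric ORA gives exact tail probabilities", {
  universe <- paste0("g", 1:10)
  s <- gene_set("s", c("g1", "g2", "g3"))
  # perfect containment: P(all 3 of 3 draws hit the 3-member set) = 1/C(10,3)
  r <- ora_hypergeom(c("g1", "g2", "g3"), s, universe)
  expect_equal(r$p_hyper, 1 / 120)
  expect_equal(r$k, 3)
  # upper tail at k = 0 is 1
  r0 <- ora_hypergeom(c("g4", "g5"), s, universe)
  expect_equal(r0$p_hyper, 1)
  expect_error(ora_hypergeom("gX", s, universe), "outside the universe")
})

test_that("ORA matches Monte-Carlo draw frequencies", {
  N <- 25; K <- 6; n <- 8
  universe <- paste0("g", seq_len(N))
  s <- gene_set("s", universe[seq_len(K)])
  for (k in c(2, 3)) {
    deg <- c(universe[seq_len(k)], universe[(K + 1):(K + n - k)])
    p <- ora_hypergeom(deg, s, universe)$p_hyper
    set.seed(100 + k)
    draws <- 20000
    hits <- vapply(seq_len(draws),
                   function(i) sum(sample.int(N, n) <= K) >= k, logical(1))
    mc <- mean(hits)
    se <- sqrt(mc * (1 - mc) / draws)
    expect_lt(abs(p - mc), 3 * se)
  }
})

test_that("set activity scores are standardized means of set genes", {
  expr <- rbind(gene1 = c(1, 3), gene2 = c(2, 2))
  colnames(expr) <- c("s1", "s2")
  sc <- set_activity_scores(expr, gene_set("s", "gene1"))
  expect_equal(unname(sc), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # constant set genes contribute zero
  sc2 <- set_activity_scores(expr, gene_set("s2", "gene2"))
  expect_equal(unname(sc2), c(0, 0))
  expect_error(set_activity_scores(expr, gene_set("s3", "missing")),
               "no members")
})

test_that("rank-sum test is exact for small samples and consistent with wilcox.test", {
  # identical groups: all midranks tie, two-sided exact p = 1
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # enumeration over C(4,2) = 6 assignments: p = 2/6
  expect_equal(ranksum_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_error(ranksum_test(1, c(1, 2)), "at least 2")

  # tie-free small samples agree exactly with stats::wilcox.test
  set.seed(14)
  for (i in 1:10) {
    a <- stats::rnorm(sample(3:8, 1)); b <- stats::rnorm(sample(3:8, 1))
    expect_equal(ranksum_test(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }

  # normal approximation is close to the exact answer at n = 8 vs 8
  for (i in 1:10) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    exact <- ranksum_test(a, b)$p_value
    approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
})
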
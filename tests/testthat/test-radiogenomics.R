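make_expr <- function(values, samples) {
  expression_matrix(values, gene_ids = rownames(values), sample_ids = samples)
}

test_that("exact linear relationships give r = +/- 1", {
  set.seed(51)
  n <- 20
  f <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "feat"))
  E <- rbind(gene_pos = 2 * f[, 1] + 1, gene_neg = -f[, 1])
  tab <- pearson_feature_gene(f, make_expr(E, rownames(f)))
  expect_equal(tab$r[tab$gene == "gene_pos"], 1, tolerance = 1e-12)
  expect_equal(tab$r[tab$gene == "gene_neg"], -1, tolerance = 1e-12)
  expect_true(all(tab$significant))
})

test_that("correlation is symmetric in its arguments", {
  set.seed(52)
  n <- 15
  f <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "feat"))
  g <- rnorm(n)
  E <- rbind(gene = g)
  tab <- pearson_feature_gene(f, make_expr(E, rownames(f)))
  expect_equal(tab$r, cor(f[, 1], g), tolerance = 1e-12)
  expect_equal(tab$p, cor.test(f[, 1], g)$p.value, tolerance = 1e-9)
})

test_that("zero-variance genes are excluded with a reason, not given r = 0", {
  n <- 12
  f <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "feat"))
  E <- rbind(flat = rep(3, n), ok = rnorm(n))
  tab <- pearson_feature_gene(f, make_expr(E, rownames(f)))
  expect_false("flat" %in% tab$gene)
  expect_true("ok" %in% tab$gene)
  expect_match(attr(tab, "excluded"), "flat")
})

test_that("null calibration at n = 48 matches the |r| > 0.4 tail", {
  set.seed(53)
  n <- 48
  f <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "feat"))
  E <- matrix(rnorm(2000 * n), 2000, n,
              dimnames = list(sprintf("g%04d", 1:2000), rownames(f)))
  tab <- pearson_feature_gene(f, make_expr(E, rownames(f)))
  # theoretical null P(|r| > 0.4) at n = 48
  t0 <- 0.4 * sqrt((n - 2) / (1 - 0.16))
  p_theory <- 2 * pt(t0, df = n - 2, lower.tail = FALSE)
  expect_lt(abs(mean(tab$significant) - p_theory), 0.01)
})

test_that("fewer than 3 shared samples is an error", {
  f <- matrix(rnorm(2), 2, 1, dimnames = list(c("a", "b"), "feat"))
  E <- rbind(g = rnorm(2))
  expect_error(pearson_feature_gene(f, make_expr(E, c("a", "b"))), ">= 3")
})

test_that("top-k ranking filters significance first, then truncates", {
  tab <- data.frame(feature = "f",
                    gene = paste0("g", 1:8),
                    r = c(0.9, 0.8, 0.5, 0.45, -0.85, -0.5, 0.2, -0.1),
                    p = c(rep(0.001, 6), 0.5, 0.9),
                    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                    FALSE, FALSE),
                    stringsAsFactors = FALSE)
  class(tab) <- c("correlation_table", "data.frame")
  pos <- top_k_genes(tab, "f", k = 200, direction = "positive")
  neg <- top_k_genes(tab, "f", k = 200, direction = "negative")
  expect_equal(pos$gene, c("g1", "g2", "g3", "g4"))   # sorted by r desc
  expect_equal(neg$gene, c("g5", "g6"))               # sorted ascending
  expect_length(intersect(pos$gene, neg$gene), 0)
  expect_equal(nrow(top_k_genes(tab, "f", k = 2)), 2) # truncation
})

test_that("hypergeometric enrichment matches direct tail evaluation", {
  universe <- paste0("g", 1:40)
  ann <- list(termA = paste0("g", 1:10), termB = paste0("g", 30:40))
  res <- hypergeometric_enrichment(paste0("g", 1:10), ann, universe)
  # list == termA exactly: P(X >= 10) with N=40, m=10, k=10
  pa <- res$p[res$term == "termA"]
  expect_equal(pa, 1 / choose(40, 10), tolerance = 1e-12)
  # disjoint term: one-sided tail p = 1
  pb <- res$p[res$term == "termB"]
  expect_equal(pb, 1)
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("random gene lists are rarely enriched", {
  set.seed(54)
  universe <- paste0("g", 1:500)
  ann <- lapply(1:20, function(i) sample(universe, 25))
  names(ann) <- paste0("term", 1:20)
  qmins <- replicate(10, {
    res <- hypergeometric_enrichment(sample(universe, 30), ann, universe)
    min(res$q)
  })
  expect_gte(mean(qmins >= 0.05), 0.8)
})

test_that("the risk score correlates through the same operation", {
  set.seed(55)
  n <- 30
  score <- rnorm(n)
  names(score) <- sprintf("s%02d", 1:n)
  E <- rbind(marker = 0.9 * scale(score)[, 1] +
               sqrt(1 - 0.81) * rnorm(n))
  tab <- pearson_feature_gene(score, make_expr(E, names(score)))
  expect_equal(tab$feature[1], "risk_score")
  expect_gt(tab$r[1], 0.6)
})
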
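test_that("age_genes flags perfect correlates and excludes constants", {
  ages <- c(5, 10, 15, 20, 25, 30)
  expr <- cbind(perfect = ages, constant = rep(3, 6),
                noise = c(2, 9, 1, 7, 3, 8))
  tab <- age_genes(expr, ages)
  expect_equal(tab$r[tab$gene == "perfect"], 1)
  expect_true(tab$significant[tab$gene == "perfect"])
  expect_true(is.na(tab$r[tab$gene == "constant"]))
  expect_true(is.na(tab$p_adj[tab$gene == "constant"]))
  expect_false(tab$significant[tab$gene == "constant"])
  expect_error(age_genes(expr[1:2, ], ages[1:2]), "3")
  expect_error(age_genes(expr[c(1, 1, 1), ], rep(5, 3)), "distinct")
})

test_that("FDR adjustment matches the BH step-up oracle", {
  set.seed(40)
  expr <- matrix(rnorm(8 * 12), 8, dimnames = list(NULL, paste0("g", 1:12)))
  ages <- seq(5, 40, length.out = 8)
  tab <- age_genes(expr, ages)
  expect_equal(tab$p_adj, bh_oracle(tab$p), tolerance = 1e-12)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  # frozen hand-set case: p = .01,.02,.03,.04,.05 all adjust to .05
  expect_equal(bh_oracle(c(.01, .02, .03, .04, .05)), rep(.05, 5))
  expect_equal(p.adjust(c(.01, .02, .03, .04, .05), "fdr"), rep(.05, 5))
})

test_that("study correlations per gene match cor.test", {
  set.seed(41)
  expr <- matrix(rnorm(10 * 5), 10, dimnames = list(NULL, paste0("g", 1:5)))
  ages <- seq(6, 33, length.out = 10)
  tab <- age_genes(expr, ages)
  for (j in 1:5) {
    ct <- cor.test(expr[, j], ages)
    expect_equal(tab$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tab$p[j], ct$p.value, tolerance = 1e-12)
  }
})

test_that("study_network rank-standardizes the upper triangle", {
  # two genes moving together: single pair gets standardized value 1
  expr2 <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 5, 9))
  net2 <- study_network(expr2)
  expect_equal(net2["a", "b"], 1)
  expect_equal(diag(net2), c(a = 1, b = 1))

  # three genes with distinct pairwise correlations: {1/3, 2/3, 1}
  set.seed(42)
  expr3 <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 5, 4),
                 c = c(5, 3, 4, 1, 2))
  net3 <- study_network(expr3)
  vals <- sort(net3[upper.tri(net3)])
  expect_equal(vals, c(1 / 3, 2 / 3, 1))

  # brute-force oracle on 8 genes: pairwise Spearman + comparison-count ranks
  expr8 <- matrix(rnorm(12 * 8), 12, dimnames = list(NULL, paste0("g", 1:8)))
  net8 <- study_network(expr8)
  cors <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    cors[i, j] <- cor(rank(expr8[, i]), rank(expr8[, j]))
  }
  ut <- cors[upper.tri(cors)]
  std <- vapply(seq_along(ut), function(k)
    (sum(ut < ut[k]) + (sum(ut == ut[k]) + 1) / 2) / length(ut), numeric(1))
  oracle <- matrix(0, 8, 8)
  oracle[upper.tri(oracle)] <- std
  oracle <- oracle + t(oracle)
  diag(oracle) <- 1
  expect_equal(unname(net8), oracle, tolerance = 1e-12)
  expect_identical(net8, t(net8))

  # invariance: a strictly increasing per-gene transform leaves it unchanged
  expect_equal(study_network(exp(expr8 / 2)), net8, tolerance = 1e-12)

  # constant gene dropped with warning
  expr8c <- cbind(expr8, flat = rep(1, 12))
  expect_warning(netc <- study_network(expr8c), "flat")
  expect_equal(dim(netc), c(8, 8))
})

test_that("aggregate_network is an elementwise mean preserving symmetry", {
  set.seed(43)
  mk_net <- function() {
    m <- matrix(runif(36), 6, 6, dimnames = list(paste0("g", 1:6),
                                                 paste0("g", 1:6)))
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  }
  n1 <- mk_net()
  expect_equal(aggregate_network(list(n1))$matrix, n1)
  expect_equal(aggregate_network(list(n1, n1))$matrix, n1)

  nets <- replicate(11, mk_net(), simplify = FALSE)
  agg <- aggregate_network(nets)
  acc <- matrix(0, 6, 6)
  for (m in nets) acc <- acc + m
  expect_equal(agg$matrix, acc / 11, tolerance = 1e-12)
  expect_equal(agg$n_datasets, 11)

  # consistent gene reordering commutes with aggregation
  ord <- c(3, 1, 2, 6, 5, 4)
  reord <- lapply(nets, function(m) m[ord, ord])
  expect_equal(aggregate_network(reord)$matrix, agg$matrix[ord, ord],
               tolerance = 1e-12)

  n_bad <- mk_net()
  dimnames(n_bad) <- list(paste0("x", 1:6), paste0("x", 1:6))
  expect_error(aggregate_network(list(n1, n_bad)), "mismatch")
})

test_that("cluster_modules recovers planted blocks and honors cut limits", {
  set.seed(44)
  n <- 40
  truth <- rep(1:2, each = n / 2)
  m <- matrix(0.1, n, n)
  m[truth == 1, truth == 1] <- 0.9
  m[truth == 2, truth == 2] <- 0.9
  m <- m + matrix(rnorm(n * n, 0, 0.01), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  net <- structure(list(genes = rownames(m), matrix = m, n_datasets = 1,
                        modules = NULL), class = "coexpr_network")
  hc <- hclust(dist(m), method = "complete")
  mid <- mean(sort(hc$height, decreasing = TRUE)[1:2])
  out <- cluster_modules(net, mid)
  expect_equal(length(unique(out$modules)), 2)
  expect_equal(adjusted_rand(out$modules, truth), 1)

  expect_equal(length(unique(cluster_modules(net, 0)$modules)), n)
  expect_equal(length(unique(cluster_modules(net, max(hc$height) + 1)$modules)),
               1)
  expect_error(cluster_modules(net, -1), "non-negative")
  # module ids ordered by size, largest first
  out2 <- cluster_modules(net, mid)
  sizes <- table(out2$modules)
  expect_true(all(diff(as.vector(sizes)) <= 0))
})

test_that("module enrichment matches hypergeometric closed forms", {
  universe <- sprintf("u%03d", 1:100)
  modules <- setNames(rep(1L, 5), universe[1:5])
  # module identical to the age set: p = 1 / C(100, 5)
  res <- module_enrichment(modules, list(sA = universe[1:5]), universe)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-9)

  # disjoint tiny set: one-sided p = 1
  res0 <- module_enrichment(modules, list(sB = universe[6:8]), universe)
  expect_equal(res0$p, 1)

  # 2x2 (a=5, b=5, c=5, d=85) against an independent factorial-sum oracle
  modules2 <- setNames(rep(1L, 10), universe[1:10])
  set2 <- universe[c(1:5, 11:15)]
  res2 <- module_enrichment(modules2, list(sC = set2), universe)
  lfact <- lgamma(seq_len(201))
  lchoose2 <- function(n, k) lfact[n + 1] - lfact[k + 1] - lfact[n - k + 1]
  tail_p <- sum(vapply(5:10, function(a)
    exp(lchoose2(10, a) + lchoose2(90, 10 - a) - lchoose2(100, 10)),
    numeric(1)))
  expect_equal(res2$p, tail_p, tolerance = 1e-9)

  # BH applied across the whole module x study grid
  modules3 <- setNames(c(1L, 1L, 2L, 2L), universe[1:4])
  res3 <- module_enrichment(modules3,
                            list(sA = universe[1:2], sB = universe[40:60]),
                            universe)
  expect_equal(res3$p_adj, bh_oracle(res3$p), tolerance = 1e-12)
})

test_that("sign-classification AUROC behaves as a tie-aware U statistic", {
  model <- structure(list(coef = c(p1 = 1, p2 = 2, n1 = -1, n2 = -2),
                          mode = "log"), class = "clock_model")
  tab_perfect <- data.frame(gene = c("p1", "p2", "n1", "n2"),
                            r = c(0.8, 0.9, -0.5, -0.7))
  expect_equal(sign_classification_auroc(model, list(s1 = tab_perfect))[["s1"]],
               1.0)
  tab_tied <- data.frame(gene = c("p1", "p2", "n1", "n2"), r = rep(0.3, 4))
  expect_equal(sign_classification_auroc(model, list(s1 = tab_tied))[["s1"]],
               0.5)
  # six hand scores against the all-pairs half-credit counting oracle
  model6 <- structure(list(coef = c(a = 1, b = 2, c = 3, d = -1, e = -2,
                                    f = -3)), class = "clock_model")
  sc <- c(a = 0.5, b = 0.1, c = 0.1, d = 0.1, e = -0.2, f = 0.4)
  tab6 <- data.frame(gene = names(sc), r = unname(sc))
  pos <- sc[c("a", "b", "c")]
  neg <- sc[c("d", "e", "f")]
  cnt <- 0
  for (p in pos) for (q in neg) cnt <- cnt + (p > q) + 0.5 * (p == q)
  expect_equal(sign_classification_auroc(model6, list(s = tab6))[["s"]],
               cnt / 9)
  mono <- structure(list(coef = c(a = 1, b = 2)), class = "clock_model")
  expect_error(sign_classification_auroc(mono, list(s = tab6)), "negative")
})
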
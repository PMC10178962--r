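test_that("DEG screen calibrates at the null rate and has power for real effects", {
  # strong effect is essentially always selected
  hits <- vapply(1:10, function(seed) {
    co <- make_gaussian_cohort(50, 50, effects = c(3, 0, 0), seed = seed)
    "G01" %in% select_degs(co, alpha = 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # null cohort selects about alpha of the genes
  frac <- vapply(1:5, function(seed) {
    co <- make_gaussian_cohort(40, 40, effects = rep(0, 100), seed = 100 + seed)
    length(select_degs(co, alpha = 0.1)) / 100
  }, numeric(1))
  expect_gt(mean(frac), 0.05)
  expect_lt(mean(frac), 0.16)
  # alpha ~ 0 selects nothing
  co <- make_gaussian_cohort(10, 10, effects = rep(0, 20), seed = 1)
  expect_length(select_degs(co, alpha = 1e-12), 0)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # degenerate: DEGs = set = universe can show no enrichment
  u <- sprintf("g%d", 1:10)
  res <- ora_enrichment(u, u, list(all = u))
  expect_equal(res$p, 1)
  # hand case: universe 20, set 5, degs 5, overlap 5 -> 1/C(20,5)
  u20 <- sprintf("g%d", 1:20)
  res2 <- ora_enrichment(u20[1:5], u20, list(s = u20[1:5]))
  expect_equal(res2$p, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: the >= 0 tail covers everything
  res3 <- ora_enrichment(u20[1:5], u20, list(s = u20[6:10]))
  expect_equal(res3$p, 1)
  # empty universe intersection flagged with p = 1
  res4 <- ora_enrichment(u20[1:5], u20, list(s = c("x", "y")))
  expect_true(res4$empty_universe)
  expect_equal(res4$p, 1)
  expect_error(ora_enrichment(c("g1", "zz"), u20, list(s = u20[1:3])),
               "outside the universe")

  # brute-force oracle: enumerate all DEG draws for small universes
  set.seed(111)
  for (rep in 1:5) {
    N <- sample(8:12, 1)
    uu <- sprintf("u%d", 1:N)
    K <- sample(2:5, 1); n <- sample(2:5, 1)
    set_members <- uu[seq_len(K)]
    degs <- sample(uu, n)
    k_obs <- length(intersect(degs, set_members))
    draws <- utils::combn(N, n)
    tail_mass <- mean(apply(draws, 2, function(ix)
      sum(uu[ix] %in% set_members) >= k_obs))
    p_pkg <- ora_enrichment(degs, uu, list(s = set_members))$p
    expect_equal(p_pkg, tail_mass, tolerance = 1e-12)
  }
})

test_that("pathway activity scores are mean member z-scores", {
  set.seed(112)
  m <- matrix(rnorm(80, 10, 3), 8, 10,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:10)))
  es <- make_es(m, stage = rep(c("PRE", "PROG"), 5))
  sets <- list(single = "g1", pair = c("g2", "g3"),
               dup = c("g2", "g3", "g3"), gone = c("zz"))
  expect_warning(sc <- pathway_sample_scores(es, sets), "gone")
  z <- t(scale(t(m)))
  expect_equal(sc["single", ], z["g1", ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sc["pair", ], colMeans(z[c("g2", "g3"), ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated members count once (sets are sets)
  expect_equal(sc["dup", ], sc["pair", ], tolerance = 1e-12)
  # invariance to per-gene affine rescaling of the raw expression
  m2 <- m * 7 - 100
  expect_warning(sc2 <- pathway_sample_scores(make_es(m2, rep(c("PRE", "PROG"), 5)), sets))
  expect_equal(sc2, sc, tolerance = 1e-9)
  # median aggregator is available
  expect_warning(scm <- pathway_sample_scores(es, sets, aggregator = stats::median))
  expect_equal(scm["pair", ], apply(z[c("g2", "g3"), ], 2, median),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("risk-score correlation selects the constructed pathways", {
  set.seed(113)
  risk <- rnorm(30); names(risk) <- sprintf("s%d", 1:30)
  noise <- matrix(rnorm(5 * 30), 5, 30,
                  dimnames = list(sprintf("n%d", 1:5), names(risk)))
  scores <- rbind(mirror = risk, anti = -risk, flat = rep(1, 30), noise)
  sel <- pathways_correlated_with_score(scores, risk)
  expect_equal(sel$rho[sel$pathway == "mirror"], 1)
  expect_equal(sel$rho[sel$pathway == "anti"], -1)
  expect_true(all(sel$selected[sel$pathway %in% c("mirror", "anti")]))
  expect_true(sel$degenerate[sel$pathway == "flat"])
  expect_false(sel$selected[sel$pathway == "flat"])
  expect_true(all(sel$p_adj >= sel$p, na.rm = TRUE))
  expect_error(pathways_correlated_with_score(scores, risk[1:10]), "missing")
})

test_that("pathway PCA index separates stages in a planted construction", {
  set.seed(114)
  stage <- rep(c("PRE", "PROG"), each = 15)
  base <- rnorm(30) + (stage == "PROG") * 2
  risk <- base; names(risk) <- sprintf("s%d", 1:30)
  scores <- t(vapply(1:6, function(i) base + rnorm(30, sd = 0.5),
                     numeric(30)))
  dimnames(scores) <- list(sprintf("p%d", 1:6), names(risk))
  pp <- pathway_pca_index(scores, stage)
  expect_length(pp$index, 30)
  expect_lt(pp$index_test$p.value, 0.01)
  expect_gt(abs(cor(pp$index, risk, method = "spearman")), 0.7)
  expect_identical(sort(unique(pp$clusters)), 1:3)
  # index test is exactly the PC-separation Kruskal-Wallis
  expect_identical(pp$index_test, pc_separation_test(pp$pca, stage, 1))
  # two identical pathways: PC1 explains everything
  two <- rbind(a = base, b = base)
  colnames(two) <- names(risk)
  pp2 <- pathway_pca_index(two, stage, k = 2)
  expect_equal(pp2$pca$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("correlation network obeys threshold and symmetry contracts", {
  set.seed(115)
  x <- rnorm(20)
  m <- rbind(a = x, b = x, c = rnorm(20), d = rep(1, 20))
  colnames(m) <- sprintf("s%d", 1:20)
  es <- make_es(m, stage = rep(c("PRE", "PROG"), 10))
  net <- correlation_network(es, threshold = 0.3)
  expect_identical(attr(net, "excluded"), "d")
  expect_true(any(net$gene_a == "a" & net$gene_b == "b" & net$rho == 1))
  expect_false(any(net$gene_a == net$gene_b))
  # strict inequality at the threshold
  expect_identical(nrow(correlation_network(es, threshold = 1)), 0L)
  # raising the threshold never adds edges
  lo <- correlation_network(es, threshold = 0.1)
  hi <- correlation_network(es, threshold = 0.5)
  expect_true(all(paste(hi$gene_a, hi$gene_b) %in% paste(lo$gene_a, lo$gene_b)))

  # block cohort: dense positive edges within blocks, negative across
  spec <- cohort_spec(sprintf("G%02d", 1:6), blocks = rep(1:2, each = 3),
                      within_cor = 0.8, between_cor = 0.5,
                      block_signs = c(1, -1), n_pre = 100, n_prog = 100,
                      seed = 116)
  net2 <- correlation_network(simulate_cohort(spec), threshold = 0.3)
  blocks <- cohort_truth(spec)$blocks
  within <- blocks[net2$gene_a] == blocks[net2$gene_b]
  expect_true(all(net2$rho[within] > 0))
  expect_true(all(net2$rho[!within] < 0))
  # SIF export round-trips as text
  f <- tempfile(fileext = ".sif")
  write_network(net2, f, "sif")
  expect_identical(length(readLines(f)), nrow(net2))
})
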
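test_that("Kruskal-Wallis matches the hand rank computation", {
  # tie-free groups (1,2,3) vs (4,5,6): H = 12/(N(N+1)) * sum ni (ri - rbar)^2
  res <- kruskal_by_stage(c(1, 2, 3, 4, 5, 6),
                          rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  expect_false(res$degenerate)
  # zero-variance convention
  res0 <- kruskal_by_stage(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(res0$degenerate)
  expect_equal(res0$p.value, 1)
  expect_error(kruskal_by_stage(1:4, c("a", "a", "a", "b")), "at least 2")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_true(all(diff(adjust_pvalues(sort(p))) >= 0))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman matrix equals hand values and Pearson-on-ranks", {
  es <- make_es(rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4),
                      z = c(4, 3, 2, 1)),
                stage = c("PRE", "PRE", "PROG", "PROG"))
  sm <- spearman_matrix(es)
  expect_equal(diag(sm$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm$rho["x", "y"], 0.8)        # 1 - 6*2/(4*15)
  expect_equal(sm$rho["x", "z"], -1)
  # oracle: Pearson correlation of the rank-transformed data
  set.seed(4)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(letters[1:5], sprintf("s%d", 1:10)))
  m[2, ] <- round(m[2, ])  # introduce ties
  es2 <- make_es(m, stage = rep(c("PRE", "PROG"), 5))
  sm2 <- spearman_matrix(es2)
  oracle <- cor(apply(m, 1, rank))  # columns = genes after apply
  expect_equal(sm2$rho, oracle, ignore_attr = TRUE, tolerance = 1e-12)
  # zero-variance gene flagged, not propagated
  m[1, ] <- 7
  sm3 <- spearman_matrix(make_es(m, stage = rep(c("PRE", "PROG"), 5)))
  expect_identical(sm3$degenerate, "a")
  expect_true(all(is.na(sm3$rho["a", ])))
  expect_false(anyNA(sm3$rho[-1, -1]))
})

test_that("hierarchical clustering recovers planted correlation blocks", {
  # two perfectly correlated pairs, anti-correlated across pairs
  rho <- rbind(c(1, 1, -1, -1), c(1, 1, -1, -1),
               c(-1, -1, 1, 1), c(-1, -1, 1, 1))
  dimnames(rho) <- list(letters[1:4], letters[1:4])
  lab <- hierarchical_clusters(rho, k = 2)
  expect_identical(lab[["a"]], lab[["b"]])
  expect_identical(lab[["c"]], lab[["d"]])
  expect_false(lab[["a"]] == lab[["c"]])
  expect_length(unique(hierarchical_clusters(rho, k = 4)), 4)
  expect_error(hierarchical_clusters(rho, k = 9), "\\[2, n_genes\\]")

  # silhouette-selected k on a generated 3-block design
  spec <- cohort_spec(sprintf("G%02d", 1:9), blocks = rep(1:3, each = 3),
                      within_cor = 0.85, between_cor = 0.2,
                      block_signs = c(1, 1, -1),
                      n_pre = 150, n_prog = 150, seed = 42)
  sm <- spearman_matrix(simulate_cohort(spec))
  lab <- hierarchical_clusters(sm)
  expect_identical(attr(lab, "k"), 3L)
  truth <- cohort_truth(spec)$blocks
  # partition must match truth up to label permutation
  expect_equal(length(unique(paste(lab, truth))), 3)
})

test_that("PCA contributions and sign convention behave as documented", {
  set.seed(9)
  x <- rnorm(20)
  es <- make_es(rbind(g1 = x, g2 = 2 * x), stage = rep(c("PRE", "PROG"), 10))
  pc <- panel_pca(es, scale. = TRUE)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-12)
  # contributions on each PC sum to 100
  expect_equal(colSums(pc$contributions), rep(100, ncol(pc$contributions)),
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive on every PC
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # variance explained invariant under sample permutation
  set.seed(10)
  m <- matrix(rnorm(80), 4, 20,
              dimnames = list(letters[1:4], sprintf("s%d", 1:20)))
  stages <- rep(c("PRE", "PROG"), 10)
  p1 <- panel_pca(make_es(m, stages))
  perm <- sample(20)
  p2 <- panel_pca(make_es(m[, perm], stages[perm]))
  expect_equal(p1$variance_explained, p2$variance_explained, tolerance = 1e-12)
  # constant gene with scaling is an error naming the gene
  m[1, ] <- 3
  expect_error(panel_pca(make_es(m, stages)), "constant gene.*a")
})

test_that("PC separation test is the Kruskal-Wallis of the component scores", {
  spec <- template_cohort_spec(seed = 12)
  co <- simulate_cohort(spec)
  pc <- panel_pca(co)
  res <- pc_separation_test(pc, stage_labels(co), 1)
  direct <- kruskal_by_stage(pc$scores[, 1], stage_labels(co))
  expect_identical(res, direct)
  expect_lt(res$p.value, 0.05)  # the template's stage effect is visible on PC1
  expect_error(pc_separation_test(pc, stage_labels(co), 99), "not exist")
})

test_that("logistic odds ratios recover a known effect and flag separation", {
  set.seed(31)
  n <- 1000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))  # true log-OR = 1 per unit
  es <- make_es(matrix(x, 1, n, dimnames = list("g", sprintf("s%d", 1:n))),
                stage = ifelse(y == 1, "PROG", "PRE"))
  tab <- gene_odds_ratios(es, standardize = FALSE)
  fit <- glm(y ~ x, family = binomial())
  se <- sqrt(diag(vcov(fit)))[["x"]]
  expect_false(tab$separation)
  expect_lt(abs(log(tab$or) - 1), 3 * se)
  expect_true(tab$ci_low <= tab$or && tab$or <= tab$ci_high)
  expect_true(tab$p_adj >= tab$p)

  # gene equal to the class indicator: flagged, not crashed
  es2 <- make_es(matrix(rep(0:1, each = 5), 1, 10,
                        dimnames = list("g", sprintf("s%d", 1:10))),
                 stage = rep(c("PRE", "PROG"), each = 5))
  tab2 <- gene_odds_ratios(es2, standardize = FALSE)
  expect_true(tab2$separation)
  expect_identical(tab2$or, Inf)
})

test_that("null odds-ratio confidence intervals cover 1 at the nominal rate", {
  set.seed(77)
  covered <- vapply(1:200, function(i) {
    x <- rnorm(400)
    y <- rbinom(400, 1, 0.5)
    es <- make_es(matrix(x, 1, 400, dimnames = list("g", sprintf("s%d", 1:400))),
                  stage = ifelse(y == 1, "PROG", "PRE"))
    tab <- gene_odds_ratios(es, standardize = FALSE)
    tab$ci_low <= 1 && 1 <= tab$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})
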
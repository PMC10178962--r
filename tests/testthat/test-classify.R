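test_that("LDA coefficients match the ridge closed form and MASS direction", {
  set.seed(51)
  Sigma <- matrix(c(1, 0.6, 0.3, 0.6, 1.2, 0.2, 0.3, 0.2, 0.8), 3, 3)
  mu1 <- c(1, 0.5, 0); mu0 <- c(0, 0, 0)
  X <- rbind(MASS::mvrnorm(1000, mu0, Sigma), MASS::mvrnorm(1000, mu1, Sigma))
  y <- rep(c(0, 1), each = 1000)
  colnames(X) <- c("a", "b", "c")
  fit <- fit_panel_lda(X, labels = y)

  # independent closed-form oracle from the same data
  S <- (cov(X[y == 1, ]) * 999 + cov(X[y == 0, ]) * 999) / 1998
  lambda <- fit$shrinkage
  oracle <- solve(S + diag(lambda, 3)) %*% (colMeans(X[y == 1, ]) - colMeans(X[y == 0, ]))
  expect_equal(unname(fit$beta), unname(drop(oracle)), tolerance = 1e-8)

  # direction within 5 degrees of the population discriminant
  pop <- solve(Sigma, mu1 - mu0)
  cosang <- sum(fit$beta * pop) / sqrt(sum(fit$beta^2) * sum(pop^2))
  expect_gt(cosang, cos(5 * pi / 180))

  # cross-check against MASS::lda's scaling direction
  ml <- MASS::lda(X, grouping = y)
  cos2 <- abs(sum(fit$beta * ml$scaling) /
                sqrt(sum(fit$beta^2) * sum(ml$scaling^2)))
  expect_gt(cos2, 0.999)

  # label swap negates the coefficients exactly: the risk score now measures
  # membership of the other class, and the orientation convention tracks
  # whichever class is labelled PROG
  fit_sw <- fit_panel_lda(X, labels = 1 - y)
  expect_equal(fit_sw$beta, -fit$beta, tolerance = 1e-12)
})

test_that("LDA is shift-invariant and scale-covariant, with shrinkage escalation", {
  co <- make_gaussian_cohort(20, 20, effects = c(1.5, 0, 0), seed = 52)
  fit <- fit_panel_lda(co)
  shifted <- co
  shifted$values <- shifted$values + 100
  expect_equal(fit_panel_lda(shifted)$beta, fit$beta, tolerance = 1e-8)

  # identity-covariance case: scaling gene i by c scales beta_i by 1/c
  set.seed(53)
  X <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, 1000)
  X[y == 1, 1] <- X[y == 1, 1] + 1
  b1 <- fit_panel_lda(X, labels = y)$beta
  X2 <- X; X2[, 1] <- X2[, 1] * 4
  b2 <- fit_panel_lda(X2, labels = y)$beta
  expect_equal(b2[["a"]], b1[["a"]] / 4, tolerance = 1e-6)

  # a duplicated gene makes the pooled covariance singular: the default
  # escalating shrinkage must still produce a finite fit
  dup <- rbind(expr_values(co), DUP = expr_values(co)[1, ])
  es <- make_es(dup, stage = as.character(stage_labels(co)))
  fit_dup <- fit_panel_lda(es)
  expect_true(all(is.finite(fit_dup$beta)))
  expect_error(fit_panel_lda(es, shrinkage = 0), "singular")

  expect_error(fit_panel_lda(co["G01", ][, 1:3]), "at least 2 samples")
  expect_error(fit_panel_lda(co, c("G01", "NOPE")), "missing.*NOPE")
})

test_that("risk scores are the pure dot product, with no intercept", {
  model <- structure(list(panel = c("a", "b"),
                          beta = c(a = 0.5, b = 2), threshold = 0,
                          class_means = c(PRE = -1, PROG = 1),
                          shrinkage = 0), class = "panel_lda")
  X <- matrix(c(4, 1), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(predict(model, X)), 4)
  # linearity: adding delta to gene i moves the score by beta_i * delta
  X2 <- X; X2[, "b"] <- X2[, "b"] + 3
  expect_equal(unname(predict(model, X2) - predict(model, X)), 2 * 3)
  # zero coefficients give zero scores
  model$beta[] <- 0
  expect_equal(unname(predict(model, X)), 0)
  # missing panel gene errors
  m <- matrix(1, 1, 1, dimnames = list("s1", "a"))
  es <- make_es(matrix(1:2, 1, 2, dimnames = list("a", c("s1", "s2"))),
                stage = c("PRE", "PROG"))
  expect_error(predict(model, es), "missing.*b")
})

test_that("AUC equals the pair statistic and the trapezoid area", {
  # worked example: scores (1,2,2,3), labels (PRE,PROG,PRE,PROG) -> 3.5/4
  s <- c(1, 2, 2, 3); l <- c("PRE", "PROG", "PRE", "PROG")
  expect_equal(roc_auc(s, l)$auc, 0.875)
  expect_equal(pairwise_auc(s, l), 0.875)
  expect_equal(trapezoid_auc(s, l), 0.875)

  expect_equal(roc_auc(c(0, 0, 5, 6), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  # dual-route identity on random vectors with heavy ties
  set.seed(61)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    s <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    l <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    a <- roc_auc(s, l)$auc
    expect_equal(a, trapezoid_auc(s, l), tolerance = 1e-12)
    expect_equal(a, pairwise_auc(s, l), tolerance = 1e-12)
    # complement symmetry under score negation
    expect_equal(a + roc_auc(-s, l)$auc, 1, tolerance = 1e-12)
  }
})

test_that("DeLong interval matches the pROC reference and stays untruncated", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- rnorm(60) + rep(c(0, 1.5), 30)
  l <- rep(c(0, 1), 30)
  mine <- roc_auc(s, l)
  ref <- pROC::ci.auc(pROC::roc(l, s, quiet = TRUE), method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(mine$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
  # near-perfect separation: the normal interval may exceed 1 by design
  s2 <- c(rnorm(15), rnorm(15) + 10); l2 <- rep(c(0, 1), each = 15)
  out <- roc_auc(s2, l2)
  expect_equal(out$auc, 1)
  expect_equal(out$ci_high, out$auc + (out$auc - out$ci_low), tolerance = 1e-12)
  clipped <- roc_auc(s2, l2, clip = TRUE)
  expect_lte(clipped$ci_high, 1)
})

test_that("optimal cutpoint maximizes Youden with deterministic tie-breaks", {
  expect_equal(optimal_cutpoint(c(1, 2, 3, 4), c("PRE", "PRE", "PROG", "PROG")),
               2.5)
  # fully separated classes: midpoint of the gap, J = 1
  cp <- optimal_cutpoint(c(0, 1, 10, 11), c(0, 0, 1, 1))
  expect_equal(cp, 5.5)
  expect_warning(cp0 <- optimal_cutpoint(rep(2, 6), rep(c(0, 1), 3)),
                 "constant")
  expect_true(is.na(cp0))
  # determinism under exchangeable ties
  set.seed(63)
  s <- sample(1:5, 30, replace = TRUE); l <- rep(c(0, 1), 15)
  expect_identical(optimal_cutpoint(s, l), optimal_cutpoint(s, l))
  # monotone transform preserves AUC and the cutpoint's rank position
  s2 <- exp(s)
  expect_equal(roc_auc(s, l)$auc, roc_auc(s2, l)$auc, tolerance = 1e-12)
  expect_equal(sum(s > optimal_cutpoint(s, l)),
               sum(s2 > optimal_cutpoint(s2, l)))
})

test_that("confusion metrics reproduce hand-computed tables and flag gaps", {
  # perfect classifier
  m <- confusion_metrics(c(1, 2, 9, 10), c(0, 0, 1, 1), 5)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv), rep(1, 4))
  expect_length(m$undefined, 0)
  # all predicted PROG: NPV undefined
  m2 <- confusion_metrics(c(3, 4, 5, 6), c(0, 0, 1, 1), 0)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  expect_true("npv" %in% m2$undefined)
  # constructed 30-sample table: TP=12 FN=1 TN=17 FP=0
  scores <- c(rep(0, 17), rep(1, 12), 0)           # last PROG miscalled
  labels <- c(rep("PRE", 17), rep("PROG", 13))
  m3 <- confusion_metrics(scores, labels, 0.5)
  expect_equal(m3$sensitivity, 12 / 13)
  expect_equal(m3$specificity, 1)
  expect_equal(m3$ppv, 1)
  expect_equal(m3$npv, 17 / 18)
  expect_error(confusion_metrics(1:4, c(0, 0, 1, 1), Inf), "finite")
})
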
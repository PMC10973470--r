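test_that("generators are reproducible from their seed", {
  sets <- synthetic_rcd_sets(100, n_sets = 6, set_size = 5, n_planted = 20,
                             seed = 1)
  b1 <- generate_bulk(30, 100, sets, seed = 2)
  b2 <- generate_bulk(30, 100, sets, seed = 2)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$truth$u, b2$truth$u)
  b3 <- generate_bulk(30, 100, sets, seed = 3)
  expect_false(identical(b1$expr, b3$expr))
  s1 <- generate_sc(40, 100, sets, seed = 4)
  s2 <- generate_sc(40, 100, sets, seed = 4)
  expect_identical(s1$expr, s2$expr)
  # generators do not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(generate_bulk(10, 100, sets, seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("zero effect leaves expression independent of the activity", {
  sets <- synthetic_rcd_sets(200, n_sets = 6, set_size = 6, n_planted = 25,
                             seed = 5)
  g <- generate_bulk(150, 200, sets, effect = 0, seed = 6)
  rhos <- vapply(g$truth$planted_genes, function(gene) {
    spearman_test(g$expr[gene, ], g$truth$u)$statistic
  }, 0)
  expect_lt(mean(abs(rhos)), 0.1)
})

test_that("default effect calibration puts planted genes near rho 0.6", {
  sets <- synthetic_rcd_sets(300, n_sets = 8, set_size = 10, n_planted = 40,
                             seed = 7)
  g <- generate_bulk(400, 300, sets, seed = 8)
  rhos <- vapply(g$truth$planted_genes, function(gene) {
    spearman_test(g$expr[gene, ], g$truth$u)$statistic
  }, 0)
  expect_gt(mean(rhos), 0.5)
  expect_lt(mean(rhos), 0.7)
})

test_that("single-cell dropout hits the requested zero fraction", {
  sets <- synthetic_rcd_sets(100, n_sets = 4, set_size = 6, n_planted = 15,
                             seed = 9)
  g <- generate_sc(5000, 100, sets, dropout_rate = 0.3, seed = 10)
  expect_lt(abs(mean(g$expr == 0) - 0.3), 0.02)
  g0 <- generate_sc(200, 100, sets, dropout_rate = 0, seed = 11)
  expect_equal(mean(g0$expr == 0), 0)
  expect_true(any(g0$malignant) && !all(g0$malignant))
  expect_error(generate_sc(100, 100, sets, dropout_rate = 1),
               "dropout_rate")
  expect_error(generate_sc(100, 100, sets, malignant_fraction = 1),
               "malignant_fraction")
})

test_that("malignant shift drives the single-cell fold-change filter", {
  sets <- synthetic_rcd_sets(150, n_sets = 6, set_size = 8, n_planted = 25,
                             seed = 12)
  g <- generate_sc(800, 150, sets, seed = 13)
  lfc <- vapply(g$truth$planted_genes, function(gene) {
    x <- g$expr[gene, ]
    log(mean(expm1(x[g$malignant])) + 1) -
      log(mean(expm1(x[!g$malignant])) + 1)
  }, 0)
  expect_gt(mean(lfc > 0.25), 0.9)
})

test_that("survival generator obeys its null, censoring and signal limits", {
  X <- withr::with_seed(14, matrix(rnorm(500 * 3), 500, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  # null: any risk ordering is uninformative
  d0 <- generate_survival(X, c(0, 0, 0), seed = 15)
  expect_lt(abs(c_index(X[, 1], d0) - 0.5), 0.05)
  # no censoring in the infinite-horizon limit
  dInf <- generate_survival(X, c(1, 0, 0), censor_horizon = Inf, seed = 16)
  expect_equal(sum(dInf$event), 500)
  # strong linear signal: the oracle risk is highly concordant
  dS <- generate_survival(X, c(2, 2, 2), baseline_rate = 0.5,
                          censor_horizon = 10, seed = 17)
  expect_gt(c_index(drop(X %*% c(2, 2, 2)), dS), 0.8)
  expect_error(generate_survival(X, c(1, 1), seed = 1), "one coefficient")
  expect_error(generate_survival(X, c(1, 1, 1), baseline_rate = 0),
               "positive")
})

test_that("logistic response labels track the link strength", {
  withr::with_seed(18, scores <- rnorm(2000))
  flat <- generate_ici(scores, slope = 0, seed = 19)
  expect_lt(abs(roc_auc(scores, flat) - 0.5), 0.05)
  steep <- generate_ici(scores, slope = 50, seed = 20)
  expect_gt(roc_auc(scores, steep), 0.97)
  # slope 2 on standardized scores gives AUC near 0.84
  mid <- generate_ici(zscore_scale(scores), slope = 2, seed = 21)
  expect_lt(abs(roc_auc(zscore_scale(scores), mid) - 0.84), 0.03)
  # target_rate controls the class imbalance
  imb <- generate_ici(scores, slope = 1, target_rate = 0.28, seed = 22)
  expect_lt(abs(mean(imb) - 0.28), 0.04)
})
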
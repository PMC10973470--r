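test_that("spearman_test matches closed-form values and flags degeneracy", {
  expect_equal(spearman_test(1:3, 1:3)$statistic, 1)
  expect_equal(spearman_test(1:3, 3:1)$statistic, -1)
  # Sum d^2 = 4 at n = 5: rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$statistic, 0.8)
  expect_true(r$p_value > 0 && r$p_value < 1)

  expect_error(spearman_test(1:4, 1:5), "same length")
  expect_error(spearman_test(1:2, 2:1), "at least 3")
  deg <- spearman_test(rep(1, 5), rnorm(5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$statistic))
})

test_that("spearman_test is invariant under strictly monotone transforms", {
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(15)
      y <- rnorm(15)
      a <- spearman_test(x, y)
      b <- spearman_test(exp(x), 3 * y - 1)
      expect_identical(a$statistic, b$statistic)
      expect_identical(a$p_value, b$p_value)
    }
  })
})

test_that("wilcoxon_rank_sum: exact small-sample path and symmetry", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  same <- c(1, 2, 3)
  expect_equal(wilcoxon_rank_sum(same, same)$p_value, 1)
  a <- c(0.3, 1.2, 2.2, 5)
  b <- c(0.8, 0.9, 4)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
  expect_error(wilcoxon_rank_sum(1, 2:3), "at least 4")
})

test_that("wilcoxon exact path tracks the normal approximation at n = 12", {
  withr::with_seed(7, {
    # near-balanced groups: with 3 or fewer observations in one group the
    # normal approximation is known to drift beyond this band
    devs <- replicate(100, {
      a <- rnorm(sample(4:8, 1))
      b <- rnorm(12 - length(a))
      p_exact <- wilcoxon_rank_sum(a, b)$p_value
      p_norm <- stats::wilcox.test(a, b, exact = FALSE,
                                   correct = TRUE)$p.value
      abs(p_exact - p_norm)
    })
    expect_lt(max(devs), 0.02)
  })
})

test_that("bh_adjust reproduces step-up minima and its basic properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
  withr::with_seed(5, {
    for (i in 1:10) {
      p <- runif(20)
      q <- bh_adjust(p)
      expect_true(all(q >= p))
      expect_true(all(q >= 0 & q <= 1))
      # monotone in rank order: sorting p sorts q the same way
      expect_true(all(diff(q[order(p)]) >= 0))
    }
  })
})

test_that("geometric_mean applies the sign policies", {
  expect_equal(geometric_mean(c(0.25, 0.64)), 0.4)
  expect_equal(geometric_mean(0.4), 0.4)
  expect_true(is.na(geometric_mean(c(0.4, -0.3))))
  expect_true(is.na(geometric_mean(c(0.4, 0))))
  expect_equal(geometric_mean(c(-0.25, -0.64)), -0.4)
  expect_equal(geometric_mean(c(0.4, -0.3), policy = "signed-abs"),
               sqrt(0.12))
  expect_equal(geometric_mean(c(-0.4, -0.3, 0.2), policy = "signed-abs"),
               -exp(mean(log(c(0.4, 0.3, 0.2)))))
  expect_error(geometric_mean(numeric(0)), "nonempty")
})

test_that("roc_auc is the Mann-Whitney statistic with tie convention 1/2", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  # complement identity, exact
  withr::with_seed(9, {
    for (i in 1:20) {
      s <- rnorm(30)
      l <- rbinom(30, 1, 0.4)
      if (sum(l) %in% c(0, 30)) next
      expect_identical(roc_auc(s, l) + roc_auc(-s, l), 1)
    }
  })
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    s <- rnorm(100)
    l <- rbinom(100, 1, plogis(s))
    expect_equal(roc_auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))))
  })
})
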
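make_bulk_screen_fixture <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n)
    expr <- rbind(
      planted = 5 + u + rnorm(n, sd = 0.3),
      noise1 = rnorm(n, 5),
      noise2 = rnorm(n, 5),
      flat = rep(2, n)
    )
    colnames(expr) <- sprintf("s%03d", seq_len(n))
  })
  list(expr = expr, scores = setNames(u, colnames(expr)))
}

test_that("bulk screen recovers a planted gene and flags constant genes", {
  fx <- make_bulk_screen_fixture(seed = 21)
  res <- screen_dataset_bulk(fx$expr, fx$scores, dataset_id = "d1")
  expect_true(res$in_gn[res$gene == "planted"])
  expect_true(res$degenerate[res$gene == "flat"])
  expect_false(res$in_gn[res$gene == "flat"])
  expect_true(all(res$in_gn == (res$passed_step1 & res$passed_step2)))
  expect_error(screen_dataset_bulk(fx$expr[, 1:4], fx$scores[1:4]),
               "at least 6")
  expect_error(screen_dataset_bulk(fx$expr, fx$scores[-1]),
               "sample counts")
})

test_that("pure-noise genes enter Gn at about the per-test error rate", {
  withr::with_seed(77, {
    n <- 150
    u <- rnorm(n)
    expr <- matrix(rnorm(1000 * n, mean = 5), 1000, n,
                   dimnames = list(sprintf("n%04d", 1:1000),
                                   sprintf("s%03d", 1:n)))
  })
  res <- screen_dataset_bulk(expr, setNames(u, colnames(expr)))
  # both steps test related hypotheses; the joint rate must stay below the
  # single-test level and above ~0 (the tests are not independent)
  rate <- mean(res$in_gn)
  expect_lt(rate, 0.05)
  expect_gt(mean(res$passed_step1), 0.01)
})

test_that("single-cell screen needs an up-shift in malignant cells", {
  withr::with_seed(31, {
    n <- 300
    mal <- rep(c(TRUE, FALSE), each = n / 2)
    u <- rnorm(n) + 0.5 * mal
    expr <- rbind(
      up = 3 + 0.8 * u + 0.4 * mal + rnorm(n, sd = 0.3),
      down = 3 + 0.8 * u - 0.6 * mal + rnorm(n, sd = 0.3),
      noise = rnorm(n, 3)
    )
    colnames(expr) <- sprintf("c%03d", seq_len(n))
  })
  scores <- setNames(u, colnames(expr))
  res <- screen_dataset_sc(expr, scores, mal)
  expect_true(res$in_gn[res$gene == "up"])
  expect_false(res$passed_step2[res$gene == "down"]) # one-sided logFC
  expect_false(res$in_gn[res$gene == "noise"])
  expect_error(screen_dataset_sc(expr, scores, rep(TRUE, n)),
               "both malignant")
})

test_that("aggregate_candidates applies the geometric-mean rule", {
  mk <- function(genes, rho, in_gn, id) {
    df <- data.frame(gene = genes, rho = rho, rho_p = 0.01, de_p = 0.01,
                     logfc = NA_real_, passed_step1 = in_gn,
                     passed_step2 = in_gn, in_gn = in_gn,
                     degenerate = FALSE, stringsAsFactors = FALSE)
    attr(df, "dataset_id") <- id
    attr(df, "level") <- "bulk"
    class(df) <- c("screen_result", "data.frame")
    df
  }
  cfg <- screen_config(min_datasets = 2)
  res <- list(
    mk(c("a", "b", "c"), c(0.40, 0.40, 0.50), c(TRUE, TRUE, TRUE), "d1"),
    mk(c("a", "b", "c"), c(0.36, 0.20, 0.60), c(TRUE, TRUE, FALSE), "d2")
  )
  tab <- aggregate_candidates(res, cfg, level = "bulk")
  # sqrt(0.4 * 0.36) = 0.3795 > 0.35 -> candidate
  expect_equal(tab$geo_mean_rho[tab$gene == "a"], sqrt(0.144))
  expect_true(tab$candidate[tab$gene == "a"])
  # sqrt(0.4 * 0.2) = 0.283 < 0.35 -> not a candidate
  expect_equal(tab$geo_mean_rho[tab$gene == "b"], sqrt(0.08))
  expect_false(tab$candidate[tab$gene == "b"])
  # only 1 contributing dataset < min_datasets -> not a candidate
  expect_false(tab$candidate[tab$gene == "c"])
  # at the single-cell threshold, gene b qualifies
  tab_sc <- aggregate_candidates(res, cfg, level = "sc")
  expect_true(tab_sc$candidate[tab_sc$gene == "b"])
})

test_that("raising thresholds never enlarges the candidate set", {
  fx <- make_bulk_screen_fixture(n = 80, seed = 5)
  res <- list(screen_dataset_bulk(fx$expr, fx$scores),
              screen_dataset_bulk(fx$expr + 0.01, fx$scores))
  loose <- aggregate_candidates(res, screen_config(min_datasets = 1,
                                                   geo_mean_threshold_bulk
                                                   = 0.2), "bulk")
  tight <- aggregate_candidates(res, screen_config(min_datasets = 1,
                                                   geo_mean_threshold_bulk
                                                   = 0.6), "bulk")
  expect_true(all(tight$gene[tight$candidate] %in%
                    loose$gene[loose$candidate]))
})

test_that("screen results do not depend on dataset order", {
  fx1 <- make_bulk_screen_fixture(n = 60, seed = 8)
  fx2 <- make_bulk_screen_fixture(n = 90, seed = 9)
  r1 <- screen_dataset_bulk(fx1$expr, fx1$scores, dataset_id = "a")
  r2 <- screen_dataset_bulk(fx2$expr, fx2$scores, dataset_id = "b")
  cfg <- screen_config(min_datasets = 1)
  t12 <- aggregate_candidates(list(r1, r2), cfg, "bulk")
  t21 <- aggregate_candidates(list(r2, r1), cfg, "bulk")
  expect_identical(t12, t21)
})

test_that("derive_signature intersects and warns on empty overlap", {
  mk_tab <- function(genes, cand) {
    df <- data.frame(gene = genes, geo_mean_rho = 0.5,
                     n_datasets = 3L, candidate = cand,
                     stringsAsFactors = FALSE)
    class(df) <- c("candidate_table", "data.frame")
    df
  }
  b <- mk_tab(c("A", "B", "C"), c(TRUE, TRUE, TRUE))
  s <- mk_tab(c("B", "C", "D"), c(TRUE, TRUE, TRUE))
  expect_identical(derive_signature(b, s), c("B", "C"))
  s2 <- mk_tab("D", TRUE)
  expect_warning(sig <- derive_signature(b, s2), "empty")
  expect_length(sig, 0)
})
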
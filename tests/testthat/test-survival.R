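test_that("log-rank scores reproduce hand cases and the zero-sum identity", {
  sc <- logrank_scores(data.frame(time = c(1, 2), event = c(1, 1)))
  expect_identical(sc$a, c(0.5, -0.5))
  expect_equal(sc$a_bar, 0)
  expect_equal(sc$s2, 0.25)
  # all censored: valid degenerate all-zero case
  cen <- logrank_scores(data.frame(time = 1:4, event = rep(0, 4)))
  expect_identical(cen$a, rep(0, 4))
  expect_true(cen$all_censored)
  # zero-sum over random no-censoring, distinct-time instances
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(2:50, 1)
      s <- logrank_scores(data.frame(time = runif(n), event = rep(1, n)))
      expect_lt(abs(sum(s$a)), 1e-12)
    }
  })
  # scores map back to input order
  d <- data.frame(time = c(3, 1, 2), event = c(1, 1, 1))
  s <- logrank_scores(d)
  expect_identical(s$a[order(d$time)], logrank_scores(d[order(d$time), ])$a)
})

test_that("split_statistic matches the hand-evaluated N=2 case", {
  sc <- logrank_scores(data.frame(time = c(1, 2), event = c(1, 1)))
  cand <- split_statistic(sc, c(0, 1), 0)
  expect_equal(cand$R1, 1)
  expect_equal(cand$M, 0.5 / sqrt(0.125))
  # complementing the split flips the sign of M
  withr::with_seed(17, {
    d <- data.frame(time = rexp(20), event = rbinom(20, 1, 0.8))
    x <- rnorm(20)
    s <- logrank_scores(d)
    m1 <- split_statistic(s, x, 0.2)$M
    m2 <- split_statistic(s, -x, -0.2)$M
    expect_equal(m1, -m2)
  })
  expect_error(split_statistic(sc, c(0, 0), 0), "degenerate split")
})

test_that("|M| of an uninformative split is on the standard-normal scale", {
  withr::with_seed(23, {
    ms <- replicate(2000, {
      n <- 60
      d <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8))
      x <- rnorm(n)
      split_statistic(logrank_scores(d), x, stats::median(x))$M
    })
  })
  q95 <- unname(stats::quantile(abs(ms), 0.95))
  expect_gt(q95, 1.7)
  expect_lt(q95, 2.25)
})

test_that("best_split equals exhaustive enumeration including tie-breaks", {
  withr::with_seed(29, {
    for (i in 1:30) {
      inst <- random_survival_instance(sample(5:25, 1), sample(2:5, 1),
                                       seed = 1000 + i,
                                       tie_prob = (i %% 3 == 0))
      sc <- logrank_scores(data.frame(time = inst$time, event = inst$event))
      if (sc$s2 <= 0) next
      got <- best_split(sc, inst$X)
      want <- oracle_best_split(sc, inst$X)
      expect_identical(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$M, want$M, tolerance = 1e-12)
    }
  })
  # duplicated feature column: tie broken toward the lower feature index
  inst <- random_survival_instance(15, 2, seed = 555)
  inst$X[, 2] <- inst$X[, 1]
  sc <- logrank_scores(data.frame(time = inst$time, event = inst$event))
  expect_identical(best_split(sc, inst$X)$feature, 1L)
  # all-constant features are an error
  constX <- matrix(1, 15, 2)
  expect_error(best_split(sc, constX), "no admissible split")
})

test_that("cox_fit matches a generic optimizer and an established fit", {
  withr::with_seed(37, {
    for (i in 1:10) {
      inst <- random_survival_instance(sample(20:40, 1), sample(1:3, 1),
                                       seed = 2000 + i)
      d <- survival_data(inst$time, inst$event, inst$X)
      fit <- cox_fit(d)
      expect_true(fit$converged)
      want <- oracle_cox_beta(inst$time, inst$event, inst$X)
      expect_lt(max(abs(unname(coef(fit)) - want)), 1e-6)
      cph <- survival::coxph(
        survival::Surv(inst$time, inst$event) ~ inst$X, ties = "breslow")
      expect_equal(unname(coef(fit)), unname(coef(cph)), tolerance = 1e-8)
      expect_equal(unname(fit$se),
                   unname(sqrt(diag(stats::vcov(cph)))), tolerance = 1e-6)
    }
  })
})

test_that("cox_fit recovers a known two-group hazard ratio", {
  withr::with_seed(41, {
    n <- 300
    grp <- rep(c(0, 1), each = n / 2)
    time <- rexp(n, rate = 0.2 * exp(log(2) * grp))
    cens <- runif(n, 0, 15)
    d <- survival_data(pmin(time, cens), as.integer(time <= cens),
                       matrix(grp, ncol = 1, dimnames = list(NULL, "grp")))
  })
  fit <- cox_fit(d)
  expect_lt(abs(coef(fit)[["grp"]] - log(2)), 3 * fit$se[["grp"]])
  expect_error(cox_fit(survival_data(1:4, rep(0, 4),
                                     matrix(rnorm(4), ncol = 1))),
               "no events")
  expect_error(cox_fit(survival_data(1:4, rep(1, 4),
                                     matrix(1, 4, 1))), "constant")
})

test_that("a covariate independent of survival gets a near-zero effect", {
  withr::with_seed(43, {
    inst <- random_survival_instance(400, 1, seed = 3000)
    fit <- cox_fit(survival_data(inst$time, inst$event, inst$X))
    z <- coef(fit) / fit$se
    expect_lt(abs(z), 4)
  })
})

test_that("stepwise_cox selects the prognostic feature and lowers AIC", {
  withr::with_seed(47, {
    hits <- 0L
    for (s in 1:10) {
      n <- 500
      X <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
      d <- generate_survival(X, c(1, rep(0, 9)), baseline_rate = 0.5,
                             censor_horizon = 10, seed = 4000 + s)
      fit <- stepwise_cox(d)
      if ("f1" %in% fit$selected) hits <- hits + 1L
      full <- suppressWarnings(cox_fit(d))
      expect_lte(fit$AIC, full$AIC + 1e-8)
      expect_true(all(diff(fit$path$aic) < 0))
    }
    expect_gte(hits, 9L)
  })
})

test_that("logrank_test behaves like a chi-square group comparison", {
  withr::with_seed(53, {
    d <- survival_data(rexp(40) + 0.1, rbinom(40, 1, 0.8))
    g <- rep(c("a", "b"), 20)
  })
  r <- logrank_test(d, g)
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # relabeling groups leaves the statistic unchanged
  g2 <- ifelse(g == "a", "x", "w")
  expect_equal(logrank_test(d, g2)$statistic, r$statistic)
  # identical groups: near-zero statistic
  d2 <- survival_data(rep(c(1, 2, 3, 4), 2), rep(1, 8))
  g3 <- rep(c("a", "b"), each = 4)
  expect_lt(logrank_test(d2, g3)$statistic, 1e-10)
  expect_error(logrank_test(d, rep("a", 40)), "at least 2 groups")
})

test_that("group sums of log-rank scores equal the log-rank O - E", {
  # the numerator of the two-group log-rank statistic is exactly the sum
  # of the per-subject log-rank scores over that group
  withr::with_seed(59, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      time <- runif(n)
      event <- rbinom(n, 1, 0.7)
      if (sum(event) < 2) event[1:2] <- 1L
      g <- rbinom(n, 1, 0.5)
      if (sum(g) %in% c(0, n)) g[1:2] <- c(0, 1)
      sc <- logrank_scores(data.frame(time = time, event = event))
      sd1 <- survival::survdiff(survival::Surv(time, event) ~ g)
      expect_equal(unname(sd1$obs[1] - sd1$exp[1]), sum(sc$a[g == 0]),
                   tolerance = 1e-10)
    }
  })
})

test_that("c_index honours the ordering and tie conventions", {
  d <- survival_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(c_index(c(4, 3, 2, 1), d), 1)
  expect_equal(c_index(c(1, 2, 3, 4), d), 0)
  expect_equal(c_index(rep(1, 4), d), 0.5)
  withr::with_seed(61, {
    inst <- random_survival_instance(60, 1, seed = 7000)
    risk <- rnorm(60)
    dd <- survival_data(inst$time, inst$event)
    got <- c_index(risk, dd)
    conc <- survival::concordance(
      survival::Surv(inst$time, inst$event) ~ risk, reverse = TRUE)
    expect_equal(got, unname(conc$concordance), tolerance = 1e-12)
  })
  expect_error(c_index(c(1, 2), survival_data(c(1, 2), c(0, 0))),
               "no admissible pairs")
})

test_that("meta_pool reproduces fixed and random effects closed forms", {
  r <- meta_pool(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(r$estimate, 0.5)
  expect_equal(r$tau2, 0)
  y <- c(0.2, 0.8, 0.5)
  se <- c(0.1, 0.3, 0.2)
  f <- meta_pool(y, se, model = "fixed")
  expect_equal(f$estimate, sum(y / se^2) / sum(1 / se^2))
  expect_gte(f$estimate, min(y))
  expect_lte(f$estimate, max(y))
  re <- meta_pool(y, se)
  expect_gte(re$tau2, 0)
  expect_gte(re$estimate, min(y))
  expect_lte(re$estimate, max(y))
  expect_true(re$ci_lower <= re$estimate && re$estimate <= re$ci_upper)
  expect_warning(single <- meta_pool(0.4, 0.2), "one study")
  expect_true(single$single_study)
  expect_error(meta_pool(c(0.1, 0.2), c(0.1, -0.2)), "positive")
})
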
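# Shared statistical primitives. Every test here is two-sided and uses
# average ranks for ties, so all downstream stages are deterministic.

new_test_result <- function(statistic, p_value, n, degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_value = p_value, n = as.integer(n),
         degenerate = degenerate),
    class = "rcd_test"
  )
}

#' @export
print.rcd_test <- function(x, ...) {
  if (x$degenerate) {
    cat("degenerate test result (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("statistic = %.6g, p = %.4g, n = %d\n",
                x$statistic, x$p_value, x$n))
  }
  invisible(x)
}

#' Spearman rank correlation test
#'
#' Spearman's rho with a two-sided p-value from the t-approximation on the
#' rank correlation (the behaviour of `cor.test(..., method = "spearman",
#' exact = FALSE)`). Constant input does not produce a silent `NaN`: it
#' returns an explicit degenerate result so callers can disqualify the gene.
#'
#' @param x,y Numeric vectors of equal length (at least 3 pairs).
#' @return An object of class `rcd_test` with fields `statistic` (rho),
#'   `p_value`, `n` and `degenerate`.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))$statistic # 0.8
#' @export
spearman_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(new_test_result(NA_real_, NA_real_, n, degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  new_test_result(unname(ct$estimate), min(max(ct$p.value, 0), 1), n)
}

#' Two-sided Wilcoxon rank sum test
#'
#' Exact enumeration of the tie-aware rank-sum distribution when the combined
#' sample size is at most 12 (all `choose(n, n_a)` group assignments), and
#' the normal approximation with tie correction and continuity correction
#' otherwise. The reported statistic is the Mann-Whitney U of the first group.
#'
#' @param a,b Numeric vectors, both nonempty, combined length at least 4.
#' @return An `rcd_test` object.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value # exactly 1/3
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(a) + length(b)
  if (n < 4) stop("need a combined sample size of at least 4", call. = FALSE)
  na <- length(a)
  r <- rank(c(a, b))
  s <- sum(r[seq_len(na)])
  u <- s - na * (na + 1) / 2
  if (n <= 12L) {
    sums <- colSums(matrix(r[utils::combn(n, na)], nrow = na))
    e <- na * (n + 1) / 2
    p <- mean(abs(sums - e) >= abs(s - e) - 1e-12)
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  new_test_result(u, min(max(p, 0), 1), n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values preserving input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Geometric mean with a sign policy
#'
#' Cross-dataset correlations are aggregated by geometric mean. Under the
#' default `"consistent-sign"` policy a gene must carry the same sign in
#' every contributing dataset: all-positive input returns
#' `exp(mean(log(v)))`, all-negative input returns the negated geometric
#' mean of the magnitudes, and mixed-sign or zero input returns `NA`
#' (the gene is disqualified). Under `"signed-abs"` the geometric mean of
#' the absolute values is given the majority sign (ties favour positive).
#'
#' @param values Nonempty numeric vector.
#' @param policy `"consistent-sign"` (default) or `"signed-abs"`.
#' @return A single number, or `NA_real_` for a disqualified gene.
#' @export
geometric_mean <- function(values,
                           policy = c("consistent-sign", "signed-abs")) {
  policy <- match.arg(policy)
  v <- as.numeric(values)
  if (length(v) == 0L) stop("`values` must be nonempty", call. = FALSE)
  if (anyNA(v)) stop("`values` must not contain NA", call. = FALSE)
  if (policy == "consistent-sign") {
    if (all(v > 0)) return(exp(mean(log(v))))
    if (all(v < 0)) return(-exp(mean(log(-v))))
    return(NA_real_)
  }
  if (any(v == 0)) return(0)
  sgn <- if (sum(v > 0) >= sum(v < 0)) 1 else -1
  sgn * exp(mean(log(abs(v))))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC: the probability that a random positive outscores a
#' random negative, ties counting one half.
#'
#' @param score Numeric scores.
#' @param label Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, label) {
  score <- as.numeric(score)
  lab <- as.integer(label)
  if (length(score) != length(lab)) {
    stop("`score` and `label` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(score))) stop("scores must be finite", call. = FALSE)
  if (!all(lab %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
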
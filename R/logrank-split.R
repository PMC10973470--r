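# Log-rank scores and the standardized split statistic they induce.
#
# With observations ordered by time (events before censorings at ties) and
# gamma_k = #{T_l <= T_k}, the score of the l-th ordered observation is
#
#   a_l = delta_l - sum_{k=1}^{gamma_l} delta_k / (N - gamma_k + 1)
#
# and a split {x <= b} with R1 left-hand samples is scored by
#
#   M(x, b) = (sum_{x_j <= b} a_j - R1 * a_bar)
#             / sqrt(R1 * (1 - R1/N) * S_a^2)
#
# where a_bar and S_a^2 are the mean and the divisor-N variance of the
# scores. |M| is approximately standard normal for an uninformative split,
# and the best split maximizes |M| over features and thresholds.

#' Log-rank scores of a survival sample
#'
#' @param data A [survival_data()] object or a data frame with `time` and
#'   `event` columns.
#' @return An object of class `logrank_scores`: `a` (scores, in input
#'   order), `N`, `a_bar`, `s2` (divisor-N variance) and `all_censored`
#'   (TRUE flags the valid degenerate all-zero case).
#' @export
logrank_scores <- function(data) {
  d <- as_survival_data(data)
  n <- length(d$time)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  sc <- logrank_scores_raw(d$time, d$event)
  structure(
    list(a = sc, N = n, a_bar = mean(sc), s2 = mean((sc - mean(sc))^2),
         all_censored = sum(d$event) == 0L),
    class = "logrank_scores"
  )
}

# Internal fast path used inside tree growing.
logrank_scores_raw <- function(time, event) {
  n <- length(time)
  ord <- order(time, -event)
  ts <- time[ord]
  ev <- event[ord]
  gamma <- findInterval(ts, ts)     # number of times <= T_k
  csum <- cumsum(ev / (n - gamma + 1))
  a <- numeric(n)
  a[ord] <- ev - csum[gamma]
  a
}

#' @export
print.logrank_scores <- function(x, ...) {
  cat(sprintf("log-rank scores: N = %d, mean = %.4g, var(N) = %.4g%s\n",
              x$N, x$a_bar, x$s2,
              if (x$all_censored) " (all censored)" else ""))
  invisible(x)
}

#' Standardized log-rank split statistic
#'
#' @param scores A [logrank_scores()] object.
#' @param x Numeric covariate vector in the same sample order.
#' @param b Threshold; the left child is `x <= b`.
#' @return A list of class `split_candidate` with `threshold`, `R1` and `M`.
#' @export
split_statistic <- function(scores, x, b) {
  stopifnot(inherits(scores, "logrank_scores"))
  x <- as.numeric(x)
  if (length(x) != scores$N) {
    stop("`x` must have one value per sample", call. = FALSE)
  }
  left <- x <= b
  r1 <- sum(left)
  n <- scores$N
  if (r1 < 1L || r1 > n - 1L) {
    stop("degenerate split: R1 must lie in [1, N-1]", call. = FALSE)
  }
  if (scores$s2 <= 0) {
    stop("zero variance of log-rank scores", call. = FALSE)
  }
  m <- (sum(scores$a[left]) - r1 * scores$a_bar) /
    sqrt(r1 * (1 - r1 / n) * scores$s2)
  structure(list(feature = NA_integer_, threshold = b, R1 = r1, M = m),
            class = "split_candidate")
}

# Vectorized scan of one feature. Returns NULL if no admissible threshold.
scan_feature <- function(scores, x, min_child_events = 0L, event = NULL) {
  o <- order(x)
  xs <- x[o]
  csum <- cumsum(scores$a[o])
  boundary <- which(diff(xs) > 0)
  if (min_child_events > 0L) {
    cev <- cumsum(event[o])
    tot <- cev[length(cev)]
    boundary <- boundary[cev[boundary] >= min_child_events &
                           tot - cev[boundary] >= min_child_events]
  }
  if (length(boundary) == 0L) return(NULL)
  r1 <- boundary
  m <- (csum[boundary] - r1 * scores$a_bar) /
    sqrt(r1 * (1 - r1 / scores$N) * scores$s2)
  i <- which.max(abs(m))            # first max: lowest threshold wins ties
  list(threshold = (xs[boundary[i]] + xs[boundary[i] + 1L]) / 2,
       R1 = r1[i], M = m[i])
}

best_split_impl <- function(scores, X, feature_subset,
                            min_child_events = 0L, event = NULL) {
  best <- NULL
  for (f in sort(unique(as.integer(feature_subset)))) {
    cand <- scan_feature(scores, X[, f], min_child_events, event)
    if (is.null(cand)) next
    if (is.null(best) || abs(cand$M) > abs(best$M)) {
      best <- c(list(feature = f), cand)
    }
  }
  best
}

#' Best log-rank-score split over features and thresholds
#'
#' Exhaustive scan of the midpoints between consecutive distinct values of
#' every feature in `feature_subset`, maximizing |M|. Ties break towards
#' the lowest feature index, then the lowest threshold.
#'
#' @param scores A [logrank_scores()] object (with `s2 > 0`).
#' @param X Numeric covariate matrix, samples x features.
#' @param feature_subset Column indices to scan (default: all).
#' @return A `split_candidate` list with `feature`, `threshold`, `R1`, `M`.
#' @export
best_split <- function(scores, X, feature_subset = seq_len(ncol(X))) {
  stopifnot(inherits(scores, "logrank_scores"))
  X <- as.matrix(X)
  if (nrow(X) != scores$N) {
    stop("`X` must have one row per sample", call. = FALSE)
  }
  if (scores$s2 <= 0) {
    stop("zero variance of log-rank scores", call. = FALSE)
  }
  best <- best_split_impl(scores, X, feature_subset)
  if (is.null(best)) {
    stop("no admissible split (all candidate features constant)",
         call. = FALSE)
  }
  structure(best, class = "split_candidate")
}
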
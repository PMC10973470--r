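# Survival model evaluation: log-rank test, Harrell's concordance, and
# random-effects pooling of per-cohort hazard ratios.

#' Log-rank test between groups
#'
#' Standard (k-group) log-rank chi-square via [survival::survdiff()].
#'
#' @param data A [survival_data()] object or compatible data frame.
#' @param groups Group labels, at least 2 nonempty groups.
#' @return An `rcd_test` with the chi-square statistic and its p-value.
#' @export
logrank_test <- function(data, groups) {
  d <- as_survival_data(data)
  g <- factor(groups)
  if (length(g) != length(d$time)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  g <- droplevels(g)
  if (nlevels(g) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  new_test_result(unname(sd$chisq), p, length(d$time))
}

#' Harrell's concordance index
#'
#' Fraction of admissible pairs (the member with the earlier time had an
#' event) that the risk score orders correctly; tied risks count one half;
#' pairs tied on time with two events are not comparable.
#'
#' @param risk Numeric risk scores (higher = riskier).
#' @param data A [survival_data()] object or compatible data frame.
#' @return Concordance in \[0, 1\].
#' @export
c_index <- function(risk, data) {
  d <- as_survival_data(data)
  risk <- as.numeric(risk)
  if (length(risk) != length(d$time)) {
    stop("`risk` must have one score per sample", call. = FALSE)
  }
  if (!all(is.finite(risk))) stop("risk scores must be finite", call. = FALSE)
  num <- 0
  den <- 0
  for (i in which(d$event == 1L)) {
    longer <- d$time > d$time[i] | (d$time == d$time[i] & d$event == 0L)
    longer[i] <- FALSE
    if (!any(longer)) next
    den <- den + sum(longer)
    num <- num + sum(risk[i] > risk[longer]) +
      0.5 * sum(risk[i] == risk[longer])
  }
  if (den == 0) stop("no admissible pairs", call. = FALSE)
  num / den
}

#' Pool log hazard ratios across cohorts
#'
#' Inverse-variance pooling with DerSimonian-Laird between-study variance
#' (`model = "random"`, the default) or the equal-effects fixed model
#' (`model = "fixed"`), via [metafor::rma()]. A single study is returned
#' unpooled with a warning and `single_study = TRUE`.
#'
#' @param log_hrs Per-cohort log hazard ratios.
#' @param ses Their positive standard errors.
#' @param model `"random"` or `"fixed"`.
#' @return A list of class `meta_result`: `estimate` (pooled log-HR), `se`,
#'   `ci_lower`, `ci_upper` (95%), `tau2`, normalized `weights`, `k`.
#' @export
meta_pool <- function(log_hrs, ses, model = c("random", "fixed")) {
  model <- match.arg(model)
  log_hrs <- as.numeric(log_hrs)
  ses <- as.numeric(ses)
  if (length(log_hrs) != length(ses)) {
    stop("`log_hrs` and `ses` must have the same length", call. = FALSE)
  }
  if (length(log_hrs) == 0L) stop("no studies supplied", call. = FALSE)
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (length(log_hrs) < 2L) {
    warning("only one study; returning it unpooled", call. = FALSE)
    return(structure(
      list(estimate = log_hrs, se = ses,
           ci_lower = log_hrs - stats::qnorm(0.975) * ses,
           ci_upper = log_hrs + stats::qnorm(0.975) * ses,
           tau2 = 0, weights = 1, k = 1L, model = model,
           single_study = TRUE),
      class = "meta_result"
    ))
  }
  fit <- metafor::rma(yi = log_hrs, sei = ses,
                      method = if (model == "random") "DL" else "EE")
  w <- as.numeric(stats::weights(fit))
  structure(
    list(estimate = as.numeric(fit$b), se = as.numeric(fit$se),
         ci_lower = as.numeric(fit$ci.lb), ci_upper = as.numeric(fit$ci.ub),
         tau2 = as.numeric(fit$tau2), weights = w / sum(w),
         k = as.integer(fit$k), model = model, single_study = FALSE),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "pooled log-HR = %.4f (HR %.3f), 95%% CI [%.4f, %.4f], tau^2 = %.4g, k = %d\n",
    x$estimate, exp(x$estimate), x$ci_lower, x$ci_upper, x$tau2, x$k))
  invisible(x)
}
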
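# Cox proportional hazards by Newton-Raphson on the Breslow-ties partial
# likelihood, plus bidirectional stepwise selection by AIC.

# Partial log-likelihood, score and observed information under Breslow
# ties. Samples are processed in decreasing time order so risk-set sums are
# prefix sums; tied times share the full risk set via the tie-group index.
cox_quantities <- function(time, event, X, beta) {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  ev <- event[ord]
  Xs <- X[ord, , drop = FALSE]
  eta <- drop(Xs %*% beta)
  w <- exp(eta)
  K <- findInterval(-ts, -ts)       # last index of each tie group
  s0 <- cumsum(w)
  s1 <- apply(Xs * w, 2L, cumsum)
  s1 <- matrix(s1, nrow = n)
  idx <- which(ev == 1L)
  ki <- K[idx]
  ll <- sum(eta[idx]) - sum(log(s0[ki]))
  xbar <- s1[ki, , drop = FALSE] / s0[ki]
  U <- colSums(Xs[idx, , drop = FALSE] - xbar)
  info <- matrix(0, p, p)
  # S2 via cumulative sums of the p(p+1)/2 distinct products
  for (a in seq_len(p)) {
    for (b in a:p) {
      s2ab <- cumsum(Xs[, a] * Xs[, b] * w)
      v <- sum(s2ab[ki] / s0[ki] - xbar[, a] * xbar[, b])
      info[a, b] <- v
      info[b, a] <- v
    }
  }
  list(loglik = ll, score = U, info = info)
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the Breslow-ties partial likelihood,
#' starting from zero, with step halving. Convergence is declared when the
#' largest score component falls below 1e-8 or the relative log-likelihood
#' change falls below 1e-10. A monotone (non-converging) likelihood is
#' reported with a warning and `converged = FALSE`. Standard errors come
#' from the inverse observed information. A dataset with zero covariate
#' columns yields the null model (useful as a stepwise starting point).
#'
#' @param data A [survival_data()] object or a data frame with `time`,
#'   `event` and feature columns; at least one event, no constant
#'   covariate.
#' @return An object of class `rcd_cox` with `coefficients`, `se`,
#'   `loglik`, `loglik_null`, `AIC`, `converged`, `n`, `nevent`.
#' @export
cox_fit <- function(data) {
  d <- as_survival_data(data)
  if (sum(d$event) < 1L) stop("no events in the data", call. = FALSE)
  X <- d$x
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(d$time), ncol = 0)
  p <- ncol(X)
  if (p > 0L) {
    rng <- apply(X, 2L, function(col) max(col) - min(col))
    if (any(rng == 0)) {
      stop("constant covariate(s): ",
           paste(colnames(X)[rng == 0], collapse = ", "), call. = FALSE)
    }
  }
  null_q <- cox_quantities(d$time, d$event, X[, 0, drop = FALSE],
                           numeric(0))
  loglik_null <- null_q$loglik
  if (p == 0L) {
    return(structure(
      list(coefficients = stats::setNames(numeric(0), character(0)),
           se = numeric(0), loglik = loglik_null,
           loglik_null = loglik_null, AIC = -2 * loglik_null,
           converged = TRUE, iter = 0L, n = length(d$time),
           nevent = sum(d$event), var = matrix(0, 0, 0)),
      class = "rcd_cox"
    ))
  }
  beta <- numeric(p)
  q <- cox_quantities(d$time, d$event, X, beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$score), error = function(e) NULL)
    if (is.null(step)) break
    newbeta <- beta + step
    newq <- cox_quantities(d$time, d$event, X, newbeta)
    halves <- 0L
    while ((!is.finite(newq$loglik) || newq$loglik < q$loglik) &&
           halves < 20L) {
      halves <- halves + 1L
      newbeta <- beta + step / 2^halves
      newq <- cox_quantities(d$time, d$event, X, newbeta)
    }
    rel <- abs(newq$loglik - q$loglik) / (abs(q$loglik) + 1e-12)
    beta <- newbeta
    q <- newq
    if (max(abs(q$score)) < 1e-8 || rel < 1e-10) {
      converged <- TRUE
      break
    }
    if (iter >= 50L) break
  }
  if (!converged || any(abs(beta) > 50)) {
    converged <- FALSE
    warning("Cox model did not converge (possibly monotone partial ",
            "likelihood)", call. = FALSE)
  }
  vcv <- tryCatch(solve(q$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(sqrt(diag(vcv)), colnames(X)),
         loglik = q$loglik, loglik_null = loglik_null,
         AIC = 2 * p - 2 * q$loglik, converged = converged, iter = iter,
         n = length(d$time), nevent = sum(d$event), var = vcv),
    class = "rcd_cox"
  )
}

#' @export
coef.rcd_cox <- function(object, ...) object$coefficients

#' @export
logLik.rcd_cox <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.rcd_cox <- function(x, ...) {
  cat(sprintf("Cox model (Breslow ties): %d samples, %d events, AIC = %.3f\n",
              x$n, x$nevent, x$AIC))
  if (length(x$coefficients)) print(x$coefficients) else cat("(null model)\n")
  invisible(x)
}

#' @export
summary.rcd_cox <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(
    coef = object$coefficients, `exp(coef)` = exp(object$coefficients),
    se = object$se, z = z, p = 2 * stats::pnorm(-abs(z)),
    check.names = FALSE
  )
  structure(list(coefficients = tab, loglik = object$loglik,
                 AIC = object$AIC, n = object$n, nevent = object$nevent,
                 converged = object$converged),
            class = "summary.rcd_cox")
}

#' @export
print.summary.rcd_cox <- function(x, ...) {
  cat(sprintf("Cox model: n = %d, events = %d, AIC = %.3f%s\n",
              x$n, x$nevent, x$AIC,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
predict.rcd_cox <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nm <- names(object$coefficients)
  if (length(nm) == 0L) return(rep(0, nrow(X)))
  if (!all(nm %in% colnames(X))) {
    stop("newdata lacks feature(s): ",
         paste(setdiff(nm, colnames(X)), collapse = ", "), call. = FALSE)
  }
  drop(X[, nm, drop = FALSE] %*% object$coefficients)
}

#' Bidirectional stepwise Cox selection by AIC
#'
#' Starts from the full model and alternately evaluates all single-feature
#' drops and additions (direction `"both"`; `"backward"`/`"forward"`
#' restrict the moves), accepting the move with the largest AIC reduction
#' until no move improves. Candidate fits that fail to converge are skipped.
#' If the full model itself cannot be fit, selection restarts from the
#' null model with a warning. Deterministic: moves are evaluated in feature
#' order and the first minimum wins ties.
#'
#' @param data A [survival_data()] object with covariates.
#' @param direction `"both"` (default), `"backward"` or `"forward"`.
#' @return The selected `rcd_cox` fit with extra fields `selected`
#'   (feature names) and `path` (data frame of accepted moves).
#' @export
stepwise_cox <- function(data, direction = c("both", "backward", "forward")) {
  direction <- match.arg(direction)
  d <- as_survival_data(data)
  if (is.null(d$x) || ncol(d$x) == 0L) {
    stop("need at least 1 candidate feature", call. = FALSE)
  }
  feats <- colnames(d$x)
  fit_subset <- function(sel) {
    fit <- tryCatch(
      suppressWarnings(cox_fit(survival_data(
        d$time, d$event,
        if (length(sel)) d$x[, sel, drop = FALSE] else NULL,
        d$sample_ids
      ))),
      error = function(e) NULL
    )
    if (!is.null(fit) && !fit$converged) fit <- NULL
    fit
  }
  current <- if (direction == "forward") character(0) else feats
  cur_fit <- fit_subset(current)
  if (is.null(cur_fit)) {
    warning("full model could not be fit; starting stepwise selection ",
            "from the null model", call. = FALSE)
    current <- character(0)
    cur_fit <- fit_subset(current)
  }
  path <- data.frame(action = "start",
                     feature = NA_character_, aic = cur_fit$AIC,
                     stringsAsFactors = FALSE)
  repeat {
    moves <- list()
    if (direction %in% c("both", "backward")) {
      for (f in intersect(feats, current)) {
        moves[[length(moves) + 1L]] <-
          list(action = "drop", feature = f, sel = setdiff(current, f))
      }
    }
    if (direction %in% c("both", "forward")) {
      for (f in setdiff(feats, current)) {
        moves[[length(moves) + 1L]] <-
          list(action = "add", feature = f,
               sel = feats[feats %in% c(current, f)])
      }
    }
    if (length(moves) == 0L) break
    aics <- vapply(moves, function(mv) {
      fit <- fit_subset(mv$sel)
      if (is.null(fit)) Inf else fit$AIC
    }, 0)
    best <- which.min(aics)          # first minimum: deterministic ties
    if (aics[best] >= cur_fit$AIC - 1e-8) break
    current <- moves[[best]]$sel
    cur_fit <- fit_subset(current)
    path <- rbind(path, data.frame(action = moves[[best]]$action,
                                   feature = moves[[best]]$feature,
                                   aic = cur_fit$AIC,
                                   stringsAsFactors = FALSE))
  }
  cur_fit$selected <- current
  cur_fit$path <- path
  cur_fit
}
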
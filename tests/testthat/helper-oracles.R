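# Independent brute-force oracles, written directly from the running-sum /
# partial-likelihood definitions with plain loops. They deliberately share
# no code with the package implementations they check.

oracle_ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  G <- nrow(expr)
  out <- matrix(0, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], rownames(expr))
    ranked <- rownames(expr)[ord]
    for (s in seq_along(sets)) {
      inset <- ranked %in% sets[[s]]
      w <- (G - seq_len(G) + 1)^alpha
      wtot <- sum(w[inset])
      nout <- G - sum(inset)
      pin <- 0; pout <- 0; es <- 0
      for (i in seq_len(G)) {
        if (inset[i]) pin <- pin + w[i] / wtot else pout <- pout + 1 / nout
        es <- es + (pin - pout)
      }
      out[s, j] <- es
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  out
}

oracle_gsva <- function(expr, sets, es_mode = "diff-of-extremes") {
  G <- nrow(expr)
  n <- ncol(expr)
  z <- matrix(0, G, n, dimnames = dimnames(expr))
  for (i in seq_len(G)) {
    h <- stats::sd(expr[i, ]) / 4
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + pnorm((expr[i, j] - expr[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  out <- matrix(0, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(expr))
    ranked <- rownames(expr)[ord]
    for (s in seq_along(sets)) {
      inset <- ranked %in% sets[[s]]
      w <- abs(seq_len(G) - (G + 1) / 2)
      wtot <- sum(w[inset])
      nout <- G - sum(inset)
      pin <- 0; pout <- 0
      v <- numeric(G)
      for (i in seq_len(G)) {
        if (inset[i]) pin <- pin + w[i] / wtot else pout <- pout + 1 / nout
        v[i] <- pin - pout
      }
      vmax <- max(c(v, 0))
      vmin <- min(c(v, 0))
      out[s, j] <- if (es_mode == "max-deviation") {
        # magnitude ties resolve to the positive extreme, as documented
        if (vmax + vmin >= -1e-12) vmax else vmin
      } else {
        vmax + vmin
      }
    }
  }
  out
}

# Exhaustive scan over every (feature, midpoint threshold) pair using the
# exported one-split statistic; ties resolved like the implementation
# claims to (lowest feature index, then lowest threshold, strict >).
oracle_best_split <- function(scores, X) {
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      b <- (xs[i] + xs[i + 1]) / 2
      cand <- split_statistic(scores, X[, f], b)
      if (is.null(best) || abs(cand$M) > abs(best$M)) {
        best <- list(feature = f, threshold = b, R1 = cand$R1, M = cand$M)
      }
    }
  }
  best
}

# Breslow partial log-likelihood written as a plain double loop; maximized
# with a generic quasi-Newton optimizer.
oracle_cox_beta <- function(time, event, X) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[rs])))
    }
    -ll
  }
  negll_grad <- function(beta) {
    eta <- drop(X %*% beta)
    g <- numeric(ncol(X))
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      w <- exp(eta[rs])
      g <- g + X[i, ] - colSums(X[rs, , drop = FALSE] * w) / sum(w)
    }
    -g
  }
  fit <- optim(rep(0, ncol(X)), negll, negll_grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  fit2 <- optim(fit$par, negll, negll_grad, method = "BFGS",
                control = list(reltol = 1e-15, maxit = 1000))
  fit2$par
}

random_survival_instance <- function(n, p, seed, censor_prob = 0.3,
                                     tie_prob = 0) {
  withr::with_seed(seed, {
    time <- rexp(n) + 0.1
    if (tie_prob > 0) {
      time <- round(time, 1) + 0.05   # coarse grid induces ties
    }
    event <- rbinom(n, 1, 1 - censor_prob)
    if (sum(event) < 2) event[1:2] <- 1L
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    list(time = time, event = event, X = X)
  })
}
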
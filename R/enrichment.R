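# Single-sample gene-set enrichment. Two scoring modes:
#   * ssgsea_scores: rank-weighted running sum, intended for bulk profiles;
#   * gsva_scores: Gaussian-kernel ECDF + symmetric-rank running sum,
#     intended for sparse single-cell profiles.
# Ranks break ties by gene identifier so both are bit-reproducible.

validate_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (nrow(expr) == 0L || ncol(expr) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    stop("gene and sample identifiers must be unique", call. = FALSE)
  }
  if (!all(is.finite(expr))) {
    stop("expression matrix must be finite (impute missing values first)",
         call. = FALSE)
  }
  expr
}

# Intersect each set with the measured genes; a set needs >= 2 measured
# members and >= 1 measured non-member to be scoreable.
resolve_sets <- function(sets, gene_ids) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (!is.list(sets) || is.null(names(sets))) {
    stop("`sets` must be a gene_set_collection or a named list",
         call. = FALSE)
  }
  out <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], gene_ids)
    if (length(g) < 2L) {
      stop("set '", nm, "' has fewer than 2 measured genes", call. = FALSE)
    }
    if (length(g) >= length(gene_ids)) {
      stop("set '", nm, "' covers every measured gene", call. = FALSE)
    }
    g
  })
  names(out) <- names(sets)
  out
}

new_enrichment <- function(scores, method, params) {
  structure(list(scores = scores, method = method, params = params),
            class = "rcd_enrichment")
}

#' @export
as.matrix.rcd_enrichment <- function(x, ...) x$scores

#' @export
print.rcd_enrichment <- function(x, ...) {
  cat(sprintf("rcd_enrichment (%s): %d set(s) x %d sample(s)\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Rank-weighted single-sample enrichment scores (ssGSEA-style)
#'
#' For each sample, genes are ranked by decreasing expression (ties broken
#' by gene identifier). Walking down that ranking, the enrichment score of
#' a set is the sum over all positions of the difference between the
#' weighted in-set ECDF and the uniform out-of-set ECDF, where the gene at
#' position `i` (of `G`) carries weight `(G - i + 1)^alpha` — the top gene
#' gets the largest weight. With `normalize = TRUE` the whole score matrix
#' is divided by its range (max - min), the usual normalization of this
#' statistic.
#'
#' @param expr Numeric matrix, genes x samples, log-scale expression with
#'   unique dimnames and no missing values.
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#'   After intersection with the measured genes every set must keep at
#'   least 2 members and leave at least 1 non-member.
#' @param alpha Nonnegative rank-weight exponent (default 0.25). `alpha = 0`
#'   gives the unweighted Kolmogorov-Smirnov running sum.
#' @param normalize Divide all scores by the matrix-wide range (default TRUE).
#' @return An `rcd_enrichment` object; `as.matrix()` extracts the
#'   sets x samples score matrix.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  expr <- validate_expr(expr)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("`alpha` must be a single nonnegative number", call. = FALSE)
  }
  ids <- rownames(expr)
  gs <- resolve_sets(sets, ids)
  ng <- nrow(expr)
  ns <- ncol(expr)
  memb <- lapply(gs, function(g) ids %in% g)
  w_base <- (ng - seq_len(ng) + 1)^alpha
  es <- matrix(0, length(gs), ns,
               dimnames = list(names(gs), colnames(expr)))
  for (j in seq_len(ns)) {
    ord <- order(-expr[, j], ids)
    for (s in seq_along(gs)) {
      mm <- memb[[s]][ord]
      win <- w_base * mm
      pin <- cumsum(win) / sum(win)
      pout <- cumsum(!mm) / (ng - sum(mm))
      es[s, j] <- sum(pin - pout)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  new_enrichment(es, "ssgsea",
                 list(alpha = alpha, normalize = normalize))
}

# Summarise a running-sum walk. "max-deviation" returns the extreme of
# the walk; when the positive and negative extremes tie in magnitude
# (within 1e-12, which exact symmetry can produce) the positive one wins,
# so the statistic does not depend on floating-point accumulation order.
gsva_es_from_runsum <- function(v, es_mode) {
  vmax <- max(c(v, 0))
  vmin <- min(c(v, 0))
  if (es_mode == "max-deviation") {
    if (vmax + vmin >= -1e-12) vmax else vmin
  } else {
    vmax + vmin
  }
}

#' Kernel-ECDF single-sample enrichment scores (GSVA-style)
#'
#' Per gene, a Gaussian-kernel cumulative density is estimated across
#' samples (bandwidth = per-gene sd / 4), turning each expression value
#' into a cross-sample quantile. Per sample, genes are ranked by decreasing
#' kernel statistic (ties broken by gene identifier); the gene at position
#' `i` carries the symmetric weight `|i - (G + 1) / 2|`, so both extremes of
#' the ranking count most. A Kolmogorov-Smirnov-like running sum over this
#' ranking gives the enrichment score, summarised either as the maximum
#' deviation from zero (`"max-deviation"`) or as the sum of the largest
#' positive and largest negative deviations (`"diff-of-extremes"`, the
#' default).
#'
#' Genes with zero variance across samples carry no information for this
#' statistic and are dropped with a warning.
#'
#' @inheritParams ssgsea_scores
#' @param es_mode `"diff-of-extremes"` (default) or `"max-deviation"`.
#' @return An `rcd_enrichment` object.
#' @export
gsva_scores <- function(expr, sets,
                        es_mode = c("diff-of-extremes", "max-deviation")) {
  es_mode <- match.arg(es_mode)
  expr <- validate_expr(expr)
  if (ncol(expr) < 2L) {
    stop("kernel-ECDF scoring needs at least 2 samples/cells", call. = FALSE)
  }
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "),
            call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(expr) < 2L) {
      stop("fewer than 2 genes with nonzero variance", call. = FALSE)
    }
  }
  ids <- rownames(expr)
  gs <- resolve_sets(sets, ids)
  ng <- nrow(expr)
  ns <- ncol(expr)
  z <- matrix(0, ng, ns, dimnames = dimnames(expr))
  for (i in seq_len(ng)) {
    xi <- expr[i, ]
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / (sds[i] / 4)))
  }
  memb <- lapply(gs, function(g) ids %in% g)
  w <- abs(seq_len(ng) - (ng + 1) / 2)
  es <- matrix(0, length(gs), ns,
               dimnames = list(names(gs), colnames(expr)))
  for (j in seq_len(ns)) {
    ord <- order(-z[, j], ids)
    for (s in seq_along(gs)) {
      mm <- memb[[s]][ord]
      win <- w * mm
      v <- cumsum(win) / sum(win) - cumsum(!mm) / (ng - sum(mm))
      es[s, j] <- gsva_es_from_runsum(v, es_mode)
    }
  }
  new_enrichment(es, "gsva", list(es_mode = es_mode, bandwidth = "sd/4"))
}
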
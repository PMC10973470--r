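# Composite RCD score and the small derived scores (CNV, CYT), plus
# sample stratification.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite RCD score
#'
#' The per-sample sum of the single-sample enrichment scores of the
#' configured number of cell-death gene sets (18 by default). The set-count
#' guard protects against accidental subsetting of the enrichment matrix.
#'
#' @param enrich An `rcd_enrichment` object or a sets x samples matrix.
#' @param n_sets Required number of sets (default 18).
#' @return Named numeric vector of per-sample scores, with attribute
#'   `level` (`"bulk-ssgsea"` or `"sc-gsva"` when known).
#' @export
rcd_score <- function(enrich, n_sets = 18L) {
  sc <- as.matrix(enrich)
  if (nrow(sc) != n_sets) {
    stop("enrichment matrix has ", nrow(sc), " set(s); expected ", n_sets,
         " (pass `n_sets` to override)", call. = FALSE)
  }
  out <- colSums(sc)
  if (inherits(enrich, "rcd_enrichment")) {
    attr(out, "level") <- switch(enrich$method,
                                 ssgsea = "bulk-ssgsea",
                                 gsva = "sc-gsva",
                                 enrich$method)
  }
  out
}

score_vector <- function(scores) {
  s <- as.numeric(scores)
  names(s) <- names(scores)
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  s
}

#' Z-score scaling
#'
#' Centre to mean 0 and scale to sample (n-1) standard deviation 1.
#'
#' @param v Numeric vector with at least 2 values and nonzero sd.
#' @return Scaled vector.
#' @export
zscore_scale <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("constant vector cannot be z-scaled", call. = FALSE)
  }
  (v - mean(v)) / s
}

#' Median split of sample scores
#'
#' Samples scoring strictly above the median are labelled `"high"`, the
#' rest `"low"` (median ties go to the low group).
#'
#' @param scores Named numeric vector of per-sample scores.
#' @return A data frame (class `rcd_strata`) with columns `sample_id`,
#'   `score`, `label`; the cutpoint is stored in attribute `cutpoint`.
#' @export
stratify_median <- function(scores) {
  s <- score_vector(scores)
  if (length(s) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (max(s) == min(s)) {
    stop("all scores identical; median split is degenerate", call. = FALSE)
  }
  cut <- stats::median(s)
  out <- data.frame(
    sample_id = names(s) %||% as.character(seq_along(s)),
    score = unname(s),
    label = ifelse(s > cut, "high", "low"),
    stringsAsFactors = FALSE
  )
  attr(out, "cutpoint") <- cut
  class(out) <- c("rcd_strata", "data.frame")
  out
}

#' Top/bottom quantile stratification
#'
#' The `floor(q * N)` highest-scoring samples are labelled `"top"`, the
#' `floor(q * N)` lowest `"bottom"`, everything else `"middle"`. Boundary
#' ties break deterministically by sample identifier.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param q Fraction in (0, 0.5].
#' @return An `rcd_strata` data frame as in [stratify_median()].
#' @export
stratify_quantile <- function(scores, q) {
  s <- score_vector(scores)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 0.5) {
    stop("`q` must lie in (0, 0.5]", call. = FALSE)
  }
  n <- length(s)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  k <- floor(q * n)
  ids <- names(s) %||% as.character(seq_along(s))
  lab <- rep("middle", n)
  lab[order(-s, ids)[seq_len(k)]] <- "top"
  lab[order(s, ids)[seq_len(k)]] <- "bottom"
  out <- data.frame(sample_id = ids, score = unname(s), label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  class(out) <- c("rcd_strata", "data.frame")
  out
}

#' Copy-number burden score
#'
#' Per sample, the sum of squared copy-number values across genes.
#'
#' @param cnv Numeric matrix, genes x samples, no missing values.
#' @return Named numeric vector of per-sample scores.
#' @export
cnv_score <- function(cnv) {
  if (!is.matrix(cnv) || !is.numeric(cnv)) {
    stop("`cnv` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(cnv))) {
    stop("`cnv` must not contain missing values", call. = FALSE)
  }
  colSums(cnv^2)
}

#' Cytolytic activity score
#'
#' Per-sample arithmetic mean of GZMA and PRF1 expression.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param genes The two marker genes (default `c("GZMA", "PRF1")`).
#' @return Named numeric vector of per-sample scores.
#' @export
cyt_score <- function(expr, genes = c("GZMA", "PRF1")) {
  expr <- validate_expr(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop("gene(s) absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  colMeans(expr[genes, , drop = FALSE])
}
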
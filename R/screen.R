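# Four-step cross-dataset screen for RCD-score-linked genes:
#   1. per-gene Spearman correlation with the composite score;
#   2. differential expression (median-split Wilcoxon for bulk, malignant
#      vs rest log fold change + Wilcoxon for single cells);
#   3. Gn = genes passing both steps within a dataset;
#   4. geometric mean of the correlations over contributing datasets,
#      thresholded per level, then bulk/single-cell intersection.

#' Screen configuration
#'
#' @param p_threshold Per-test p-value threshold (default 0.05).
#' @param sc_logfc_threshold Minimum malignant-vs-rest natural-log fold
#'   change for the single-cell differential step (default 0.25).
#' @param geo_mean_threshold_bulk Geometric-mean correlation threshold for
#'   bulk candidates (default 0.35).
#' @param geo_mean_threshold_sc Geometric-mean correlation threshold for
#'   single-cell candidates (default 0.2).
#' @param min_datasets Minimum number of datasets in which a gene must pass
#'   steps 1-2 before its geometric mean counts (default 3).
#' @param sign_policy Sign policy for [geometric_mean()].
#' @param adjust_p Apply Benjamini-Hochberg adjustment to the per-dataset
#'   p-values before thresholding (default FALSE: raw per-test level).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.05,
                          sc_logfc_threshold = 0.25,
                          geo_mean_threshold_bulk = 0.35,
                          geo_mean_threshold_sc = 0.2,
                          min_datasets = 3L,
                          sign_policy = c("consistent-sign", "signed-abs"),
                          adjust_p = FALSE) {
  sign_policy <- match.arg(sign_policy)
  for (v in c(p_threshold, sc_logfc_threshold,
              geo_mean_threshold_bulk, geo_mean_threshold_sc)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("screen thresholds must be positive numbers", call. = FALSE)
    }
  }
  min_datasets <- as.integer(min_datasets)
  if (min_datasets < 1L) stop("`min_datasets` must be >= 1", call. = FALSE)
  structure(
    list(p_threshold = p_threshold,
         sc_logfc_threshold = sc_logfc_threshold,
         geo_mean_threshold_bulk = geo_mean_threshold_bulk,
         geo_mean_threshold_sc = geo_mean_threshold_sc,
         min_datasets = min_datasets,
         sign_policy = sign_policy,
         adjust_p = isTRUE(adjust_p)),
    class = "screen_config"
  )
}

align_scores <- function(scores, sample_ids) {
  s <- score_vector(scores)
  if (length(s) != length(sample_ids)) {
    stop("scores and expression have different sample counts", call. = FALSE)
  }
  if (!is.null(names(s))) {
    if (!setequal(names(s), sample_ids)) {
      stop("sample identifiers of scores and expression do not match",
           call. = FALSE)
    }
    s <- s[sample_ids]
  }
  s
}

maybe_adjust <- function(p, cfg) {
  if (!cfg$adjust_p) return(p)
  ok <- !is.na(p)
  p[ok] <- bh_adjust(p[ok])
  p
}

new_screen_result <- function(df, dataset_id, level) {
  attr(df, "dataset_id") <- dataset_id
  attr(df, "level") <- level
  class(df) <- c("screen_result", "data.frame")
  df
}

#' Screen one bulk dataset against the RCD score
#'
#' Step 1: per-gene Spearman correlation with the composite score (pass if
#' p < threshold and |rho| > 0). Step 2: Wilcoxon rank sum between the
#' median-split high and low score groups (pass if p < threshold).
#' Constant genes are excluded with a `degenerate` flag.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param scores Per-sample composite scores aligned with `expr` columns
#'   (matched by name when named).
#' @param cfg A [screen_config()].
#' @param dataset_id Identifier recorded in the result.
#' @return A data frame (class `screen_result`) with per-gene columns
#'   `rho`, `rho_p`, `de_p`, `logfc` (NA for bulk), `passed_step1`,
#'   `passed_step2`, `in_gn`, `degenerate`.
#' @export
screen_dataset_bulk <- function(expr, scores, cfg = screen_config(),
                                dataset_id = "bulk") {
  expr <- validate_expr(expr)
  stopifnot(inherits(cfg, "screen_config"))
  if (ncol(expr) < 6L) stop("need at least 6 samples", call. = FALSE)
  s <- align_scores(scores, colnames(expr))
  strata <- stratify_median(s)
  hi <- strata$label == "high"
  screen_core(expr, s, hi_group = hi, cfg = cfg, logfc_filter = FALSE,
              dataset_id = dataset_id, level = "bulk")
}

#' Screen one single-cell dataset against the RCD score
#'
#' Step 1 as in [screen_dataset_bulk()], computed over cells. Step 2: the
#' gene must be up in malignant cells — natural-log fold change of
#' malignant vs other cells, computed on the `expm1` scale with a
#' pseudocount of 1 (`log(mean(expm1(x_mal)) + 1) -
#' log(mean(expm1(x_rest)) + 1)`, the usual convention for log-normalized
#' single-cell data), above `sc_logfc_threshold`, with Wilcoxon p below the
#' p threshold.
#'
#' @inheritParams screen_dataset_bulk
#' @param malignant Logical (or 0/1) vector marking malignant cells; both
#'   classes must be present.
#' @return A `screen_result` data frame (the `logfc` column is filled).
#' @export
screen_dataset_sc <- function(expr, scores, malignant,
                              cfg = screen_config(), dataset_id = "sc") {
  expr <- validate_expr(expr)
  stopifnot(inherits(cfg, "screen_config"))
  mal <- as.logical(malignant)
  if (length(mal) != ncol(expr) || anyNA(mal)) {
    stop("`malignant` must be a binary label per cell", call. = FALSE)
  }
  if (!any(mal) || all(mal)) {
    stop("both malignant and non-malignant cells must be present",
         call. = FALSE)
  }
  if (ncol(expr) < 6L) stop("need at least 6 cells", call. = FALSE)
  s <- align_scores(scores, colnames(expr))
  screen_core(expr, s, hi_group = mal, cfg = cfg, logfc_filter = TRUE,
              dataset_id = dataset_id, level = "sc")
}

screen_core <- function(expr, s, hi_group, cfg, logfc_filter,
                        dataset_id, level) {
  genes <- rownames(expr)
  ng <- length(genes)
  rho <- rho_p <- de_p <- logfc <- rep(NA_real_, ng)
  degen <- logical(ng)
  for (i in seq_len(ng)) {
    x <- expr[i, ]
    if (max(x) == min(x)) {
      degen[i] <- TRUE
      next
    }
    st <- spearman_test(x, s)
    if (st$degenerate) {
      degen[i] <- TRUE
      next
    }
    rho[i] <- st$statistic
    rho_p[i] <- st$p_value
    de_p[i] <- wilcoxon_rank_sum(x[hi_group], x[!hi_group])$p_value
    if (logfc_filter) {
      logfc[i] <- log(mean(expm1(x[hi_group])) + 1) -
        log(mean(expm1(x[!hi_group])) + 1)
    }
  }
  rho_p_adj <- maybe_adjust(rho_p, cfg)
  de_p_adj <- maybe_adjust(de_p, cfg)
  passed1 <- !degen & !is.na(rho_p_adj) &
    rho_p_adj < cfg$p_threshold & abs(rho) > 0
  passed2 <- !degen & !is.na(de_p_adj) & de_p_adj < cfg$p_threshold
  if (logfc_filter) passed2 <- passed2 & !is.na(logfc) &
      logfc > cfg$sc_logfc_threshold
  df <- data.frame(
    gene = genes, rho = rho, rho_p = rho_p, de_p = de_p, logfc = logfc,
    passed_step1 = passed1, passed_step2 = passed2,
    in_gn = passed1 & passed2, degenerate = degen,
    stringsAsFactors = FALSE
  )
  new_screen_result(df, dataset_id, level)
}

#' Aggregate per-dataset screens into a candidate table
#'
#' For each gene, the geometric mean of its Spearman correlations over the
#' datasets where it entered Gn (passed steps 1 and 2). A gene is a
#' candidate when that mean exceeds the level's threshold and the gene
#' contributed in at least `min_datasets` datasets. Genes measured in only
#' some datasets contribute only where measured.
#'
#' @param results List of `screen_result` data frames.
#' @param cfg A [screen_config()].
#' @param level `"bulk"` or `"sc"` (selects the threshold).
#' @return A data frame (class `candidate_table`) with columns `gene`,
#'   `geo_mean_rho`, `n_datasets`, `candidate`.
#' @export
aggregate_candidates <- function(results, cfg = screen_config(),
                                 level = c("bulk", "sc")) {
  level <- match.arg(level)
  stopifnot(inherits(cfg, "screen_config"))
  if (!is.list(results) || length(results) == 0L) {
    stop("`results` must be a nonempty list of screen results", call. = FALSE)
  }
  thr <- if (level == "bulk") cfg$geo_mean_threshold_bulk
         else cfg$geo_mean_threshold_sc
  contrib <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "screen_result"))
    r[r$in_gn, c("gene", "rho")]
  }))
  if (nrow(contrib) == 0L) {
    out <- data.frame(gene = character(0), geo_mean_rho = numeric(0),
                      n_datasets = integer(0), candidate = logical(0))
  } else {
    rho_by_gene <- split(contrib$rho, contrib$gene)
    genes <- sort(names(rho_by_gene))
    geo <- vapply(genes, function(g) {
      geometric_mean(rho_by_gene[[g]], policy = cfg$sign_policy)
    }, 0)
    nd <- vapply(genes, function(g) length(rho_by_gene[[g]]), 0L)
    out <- data.frame(
      gene = genes, geo_mean_rho = unname(geo), n_datasets = unname(nd),
      candidate = !is.na(geo) & geo > thr & nd >= cfg$min_datasets,
      stringsAsFactors = FALSE
    )
  }
  attr(out, "level") <- level
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Derive the final signature
#'
#' The RCD signature is the intersection of the bulk-level and
#' single-cell-level candidate genes. An empty intersection returns an
#' empty signature with a warning.
#'
#' @param bulk,sc `candidate_table` data frames from
#'   [aggregate_candidates()].
#' @return Sorted character vector of signature genes.
#' @export
derive_signature <- function(bulk, sc) {
  stopifnot(inherits(bulk, "candidate_table"),
            inherits(sc, "candidate_table"))
  sig <- sort(intersect(bulk$gene[bulk$candidate], sc$gene[sc$candidate]))
  if (length(sig) == 0L) {
    warning("bulk and single-cell candidates do not intersect; ",
            "returning an empty signature", call. = FALSE)
  }
  sig
}
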
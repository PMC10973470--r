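# CRISPR screen rank aggregation. Score orientation: lower = stronger
# effect (more essential / stronger immune phenotype on knockout).

#' Mean CRISPR scores per gene
#'
#' Per-gene mean over the datasets where the gene was measured (missing
#' entries are ignored), ranked ascending so the strongest effects come
#' first. `rank_aggregate = TRUE` averages per-dataset ranks instead of raw
#' scores.
#'
#' @param m Numeric matrix, genes x datasets, `NA` allowed; every gene must
#'   be measured at least once.
#' @param rank_aggregate Aggregate per-dataset ranks rather than raw
#'   scores (default FALSE, matching the mean-score convention).
#' @return A data frame (class `crispr_rank`) ordered by ascending
#'   `mean_score` (gene id breaks ties) with columns `gene`, `mean_score`,
#'   `n_datasets`.
#' @export
mean_rank_scores <- function(m, rank_aggregate = FALSE) {
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0L) {
    stop("`m` must be a nonempty numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m))) {
    stop("`m` needs gene rownames", call. = FALSE)
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    warning("duplicated dataset columns enter the mean multiply",
            call. = FALSE)
  }
  meas <- rowSums(!is.na(m))
  if (any(meas == 0)) {
    stop("gene(s) with no measurements: ",
         paste(utils::head(rownames(m)[meas == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  vals <- if (rank_aggregate) {
    apply(m, 2L, function(col) rank(col, na.last = "keep"))
  } else {
    m
  }
  ms <- rowMeans(vals, na.rm = TRUE)
  out <- data.frame(gene = rownames(m), mean_score = unname(ms),
                    n_datasets = unname(meas), stringsAsFactors = FALSE)
  out <- out[order(out$mean_score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("crispr_rank", "data.frame")
  out
}

#' Top fraction of a ranked gene table
#'
#' The `floor(q * G)` genes with the lowest mean scores.
#'
#' @param table A `crispr_rank` data frame from [mean_rank_scores()].
#' @param q Fraction in (0, 1); default 0.10.
#' @return Sorted character vector of gene identifiers (empty with a
#'   warning when the fraction selects no gene).
#' @export
top_fraction <- function(table, q = 0.10) {
  stopifnot(inherits(table, "crispr_rank"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must lie in (0, 1)", call. = FALSE)
  }
  k <- floor(q * nrow(table))
  if (k == 0L) {
    warning("fraction selects no genes", call. = FALSE)
    return(character(0))
  }
  sort(table$gene[seq_len(k)])
}

#' Intersect screen hits with a signature
#'
#' @param a,b Gene sets (character vectors), e.g. cell-fitness and
#'   immune-screen hits.
#' @param signature Signature gene set.
#' @return Sorted intersection `a` ∩ `b` ∩ `signature`.
#' @export
intersect_hits <- function(a, b, signature) {
  sort(intersect(intersect(as.character(a), as.character(b)),
                 as.character(signature)))
}
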
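# Plain-text readers and writers: TSV expression/score tables, MTX triplet
# directories for single-cell matrices, survival tables.

#' Read a genes x samples expression matrix from TSV/CSV
#'
#' The first column holds gene identifiers, the header holds sample
#' identifiers.
#'
#' @param path File path; `sep` defaults to tab, use `","` for CSV.
#' @param sep Field separator.
#' @return A validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          row.names = 1L)
  validate_expr(as.matrix(df))
}

#' Write a genes x samples matrix as TSV
#'
#' @param expr Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the identifier column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, id_col = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an MTX triplet directory
#'
#' Expects `matrix.mtx` (MatrixMarket), `genes.tsv` (one gene per line)
#' and `barcodes.tsv` (one cell per line), the common single-cell layout.
#'
#' @param dir Directory containing the three files.
#' @return A dense numeric matrix, genes x cells.
#' @export
read_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing MTX component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(paths[1L]))
  genes <- readLines(paths[2L], warn = FALSE)
  cells <- readLines(paths[3L], warn = FALSE)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions do not match gene/barcode files", call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  validate_expr(m)
}

#' Write an MTX triplet directory
#'
#' @param expr Numeric matrix, genes x cells, with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(expr, dir) {
  expr <- validate_expr(expr)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(expr, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr), file.path(dir, "genes.tsv"))
  writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# Expression input dispatch: a directory is an MTX triplet, a file is TSV.
read_expression_any <- function(path) {
  if (dir.exists(path)) read_mtx(path) else read_expression(path)
}

#' Read a survival table from TSV
#'
#' Columns: `sample_id`, `time`, `event`, then optional numeric feature
#' columns.
#'
#' @param path File path.
#' @return A [survival_data()] object.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  survival_data(df$time, df$event,
                if (length(extra)) as.matrix(df[extra]) else NULL,
                df$sample_id)
}

#' Write a survival table as TSV
#'
#' @param data A [survival_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(data, path) {
  d <- as_survival_data(data)
  df <- data.frame(sample_id = d$sample_ids, time = d$time,
                   event = d$event, stringsAsFactors = FALSE)
  if (!is.null(d$x)) df <- cbind(df, as.data.frame(d$x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene x dataset CRISPR score matrix from TSV
#'
#' First column gene identifiers; empty cells become `NA`.
#'
#' @param path File path.
#' @return Numeric matrix with possible `NA` entries.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(utils::read.delim(path, check.names = FALSE, row.names = 1L))
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
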
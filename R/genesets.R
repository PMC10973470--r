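# Gene-set collections. Gene identifiers are matched case-sensitively as
# plain strings; symbols must be pre-harmonized by the caller.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (one per set). Duplicate
#'   genes within a set are removed with a warning; empty sets and
#'   duplicated set names are errors.
#' @param rcd_type Optional character vector of cell-death-type labels,
#'   one per set.
#' @param provenance Optional character vector of free-text provenance,
#'   one per set (stored in the GMT description field).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, rcd_type = NULL, provenance = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list", call. = FALSE)
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || any(!nzchar(nm)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  sets <- lapply(seq_along(sets), function(i) {
    g <- as.character(sets[[i]])
    if (length(g) == 0L) {
      stop("gene set '", nm[i], "' is empty", call. = FALSE)
    }
    if (anyDuplicated(g)) {
      warning("duplicate gene identifiers removed from set '", nm[i], "'",
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  names(sets) <- nm
  fill <- function(v, default) {
    if (is.null(v)) return(stats::setNames(rep(default, length(sets)), nm))
    if (length(v) != length(sets)) {
      stop("per-set annotation has wrong length", call. = FALSE)
    }
    stats::setNames(as.character(v), nm)
  }
  structure(
    list(sets = sets,
         rcd_type = fill(rcd_type, NA_character_),
         provenance = fill(provenance, "")),
    class = "gene_set_collection"
  )
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "set(s)\n")
  for (nm in utils::head(names(x), 10)) {
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description, then gene identifiers. Duplicate genes within a line are
#' deduplicated with a warning; a line with fewer than three fields or a
#' duplicated set name is an error naming the offending line.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("line %d of '%s' has %d field(s); GMT needs at least 3",
                 lineno[bad], path, nf[bad]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in '", path, "': ", nm[duplicated(nm)][1L],
         call. = FALSE)
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nm
  gene_set_collection(sets, provenance = desc)
}

#' Write a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection$provenance[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Merge gene sets by cell-death type
#'
#' Signatures gathered from different sources are merged per type of
#' regulated cell death: the output has one set per type whose genes are
#' the union of all input sets mapped to that type.
#'
#' @param collection A [gene_set_collection()].
#' @param type_map Named character vector mapping every set name to a type.
#' @return A [gene_set_collection()] with one set per type, named by type,
#'   in order of first appearance.
#' @export
merge_by_type <- function(collection, type_map) {
  stopifnot(inherits(collection, "gene_set_collection"))
  unmapped <- setdiff(names(collection), names(type_map))
  if (length(unmapped) > 0) {
    stop("unmapped set name(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  types <- unique(unname(type_map[names(collection)]))
  merged <- lapply(types, function(ty) {
    src <- names(collection)[type_map[names(collection)] == ty]
    sort(unique(unlist(collection$sets[src], use.names = FALSE)))
  })
  names(merged) <- types
  prov <- vapply(types, function(ty) {
    src <- names(collection)[type_map[names(collection)] == ty]
    paste("merged from:", paste(src, collapse = ","))
  }, "")
  gene_set_collection(merged, rcd_type = types, provenance = prov)
}

#' Genes shared by at least k sets
#'
#' @param collection A [gene_set_collection()].
#' @param k Minimum number of sets a gene must belong to (1 to the number
#'   of sets in the collection).
#' @return Sorted character vector of gene identifiers.
#' @export
membership_counts <- function(collection, k) {
  stopifnot(inherits(collection, "gene_set_collection"))
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > length(collection)) {
    stop("`k` exceeds the number of sets (", length(collection), ")",
         call. = FALSE)
  }
  tab <- table(unlist(collection$sets, use.names = FALSE))
  sort(names(tab)[tab >= k])
}
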
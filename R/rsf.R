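# Random survival forest with the log-rank-score split rule.
#
# Each tree is grown on a bootstrap sample; at every node the log-rank
# scores are recomputed from the node's own (time, event) data, a random
# mtry-subset of features is scanned with the standardized statistic
# M(x, b), and the split maximizing |M| is taken. Splitting stops when a
# node has fewer than 2 * min_terminal_events events or no admissible
# split leaves min_terminal_events events in each child. Terminal nodes
# store the Nelson-Aalen cumulative hazard evaluated on the tree's own
# event-time grid; the ensemble mortality of a sample is the mean over
# trees of its terminal cumulative hazard summed over that grid.

#' Fit a log-rank-score random survival forest
#'
#' @param data A [survival_data()] object (or compatible data frame) with
#'   covariates; at least 2 events.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per node (default `ceiling(sqrt(p))`).
#' @param min_terminal_events Minimum events per terminal node (default 3).
#' @param bootstrap Resample with replacement per tree (default TRUE;
#'   FALSE grows every tree on the full sample, useful for oracle checks).
#' @param seed Integer seed making the forest bit-reproducible; the
#'   caller's RNG state is left untouched.
#' @return An object of class `rcd_rsf` with the trees, out-of-bag
#'   mortality (`oob_mortality`, NA where a sample was never out of bag)
#'   and in-sample ensemble mortality (`mortality`).
#' @export
rsf_fit <- function(data, ntree = 500L, mtry = NULL,
                    min_terminal_events = 3L, bootstrap = TRUE,
                    seed = NULL) {
  d <- as_survival_data(data)
  if (is.null(d$x) || ncol(d$x) == 0L) {
    stop("covariates are required to grow a forest", call. = FALSE)
  }
  if (sum(d$event) < 2L) stop("need at least 2 events", call. = FALSE)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > p) {
    stop("`mtry` must lie in [1, number of features]", call. = FALSE)
  }
  ntree <- as.integer(ntree)
  min_terminal_events <- as.integer(min_terminal_events)
  if (ntree < 1L || min_terminal_events < 1L) {
    stop("`ntree` and `min_terminal_events` must be positive", call. = FALSE)
  }
  n <- length(d$time)
  grow_all <- function() {
    lapply(seq_len(ntree), function(t) {
      idx0 <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      grow_tree(d, idx0, p, mtry, min_terminal_events)
    })
  }
  trees <- if (is.null(seed)) grow_all() else withr::with_seed(seed, grow_all())
  fit <- structure(
    list(trees = trees, ntree = ntree, mtry = mtry,
         min_terminal_events = min_terminal_events, bootstrap = bootstrap,
         seed = seed, features = colnames(d$x), n = n,
         nevent = sum(d$event)),
    class = "rcd_rsf"
  )
  fit$mortality <- stats::setNames(rsf_predict(fit, d$x), d$sample_ids)
  fit$oob_mortality <- stats::setNames(oob_mortality(fit, d$x), d$sample_ids)
  fit
}

grow_tree <- function(d, idx0, p, mtry, min_terminal_events) {
  grid <- sort(unique(d$time[idx0][d$event[idx0] == 1L]))
  grow <- function(idx) {
    if (sum(d$event[idx]) < 2L * min_terminal_events) {
      return(make_leaf(d, idx, grid))
    }
    a <- logrank_scores_raw(d$time[idx], d$event[idx])
    s2 <- mean((a - mean(a))^2)
    if (s2 <= 0) return(make_leaf(d, idx, grid))
    sc <- list(a = a, N = length(idx), a_bar = mean(a), s2 = s2)
    feats <- sort(sample.int(p, mtry))
    bs <- best_split_impl(sc, d$x[idx, , drop = FALSE], feats,
                          min_child_events = min_terminal_events,
                          event = d$event[idx])
    if (is.null(bs)) return(make_leaf(d, idx, grid))
    left <- idx[d$x[idx, bs$feature] <= bs$threshold]
    right <- idx[d$x[idx, bs$feature] > bs$threshold]
    list(split = TRUE, feature = bs$feature, threshold = bs$threshold,
         left = grow(left), right = grow(right))
  }
  list(inbag = tabulate(idx0, nbins = length(d$time)),
       grid = grid, root = grow(idx0))
}

# Nelson-Aalen cumulative hazard of the node sample, evaluated at the
# tree-level event-time grid, stored as its grid-sum (the node mortality).
make_leaf <- function(d, idx, grid) {
  tt <- d$time[idx]
  ev <- d$event[idx]
  et <- sort(unique(tt[ev == 1L]))
  if (length(et) == 0L || length(grid) == 0L) {
    return(list(split = FALSE, mortality = 0))
  }
  dd <- vapply(et, function(s) sum(tt == s & ev == 1L), 0)
  yy <- vapply(et, function(s) sum(tt >= s), 0)
  chf <- cumsum(dd / yy)
  pos <- findInterval(grid, et)
  chf_grid <- c(0, chf)[pos + 1L]
  list(split = FALSE, mortality = sum(chf_grid))
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(nd, idx) {
    if (length(idx) == 0L) return(invisible())
    if (!nd$split) {
      out[idx] <<- nd$mortality
      return(invisible())
    }
    go_left <- X[idx, nd$feature] <= nd$threshold
    recurse(nd$left, idx[go_left])
    recurse(nd$right, idx[!go_left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

check_forest_features <- function(forest, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !all(forest$features %in% colnames(X))) {
    missing <- setdiff(forest$features, colnames(X))
    stop("prediction data lacks feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X[, forest$features, drop = FALSE]
}

#' Ensemble mortality predictions from a survival forest
#'
#' @param forest An `rcd_rsf` fit.
#' @param X Numeric matrix, samples x features, with the training feature
#'   names among its columns.
#' @return Nonnegative mortality per sample; larger means higher risk.
#' @export
rsf_predict <- function(forest, X) {
  stopifnot(inherits(forest, "rcd_rsf"))
  X <- check_forest_features(forest, X)
  preds <- vapply(forest$trees, function(tr) predict_tree(tr$root, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

oob_mortality <- function(forest, X) {
  X <- check_forest_features(forest, X)
  n <- nrow(X)
  tot <- numeric(n)
  cnt <- numeric(n)
  for (tr in forest$trees) {
    oob <- which(tr$inbag == 0L)
    if (length(oob) == 0L) next
    tot[oob] <- tot[oob] + predict_tree(tr$root, X[oob, , drop = FALSE])
    cnt[oob] <- cnt[oob] + 1
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' @export
predict.rcd_rsf <- function(object, newdata, ...) {
  rsf_predict(object, newdata)
}

#' @export
print.rcd_rsf <- function(x, ...) {
  cat(sprintf(paste0("log-rank-score survival forest: %d trees, mtry = %d,",
                     " %d samples (%d events), %d feature(s)\n"),
              x$ntree, x$mtry, x$n, x$nevent, length(x$features)))
  invisible(x)
}

#' Serialize a survival forest to JSON
#'
#' The format is a plain JSON object with the forest parameters and the
#' nested split/leaf structure of every tree, so models survive across
#' sessions without binary artifacts.
#'
#' @param forest An `rcd_rsf` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rsf_json <- function(forest, path) {
  stopifnot(inherits(forest, "rcd_rsf"))
  strip <- function(nd) {
    if (!nd$split) return(list(split = FALSE, mortality = nd$mortality))
    list(split = TRUE, feature = nd$feature, threshold = nd$threshold,
         left = strip(nd$left), right = strip(nd$right))
  }
  obj <- list(
    format = "rcdsig-rsf-1",
    ntree = forest$ntree, mtry = forest$mtry,
    min_terminal_events = forest$min_terminal_events,
    bootstrap = forest$bootstrap, features = as.list(forest$features),
    n = forest$n, nevent = forest$nevent,
    trees = lapply(forest$trees, function(tr) strip(tr$root))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a survival forest serialized by [write_rsf_json()]
#'
#' @param path Path to the JSON model file.
#' @return An `rcd_rsf` object usable with [rsf_predict()] (out-of-bag
#'   information is not serialized).
#' @export
read_rsf_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "rcdsig-rsf-1")) {
    stop("not an rcdsig survival-forest JSON file: ", path, call. = FALSE)
  }
  revive <- function(nd) {
    if (!isTRUE(nd$split)) {
      return(list(split = FALSE, mortality = as.numeric(nd$mortality)))
    }
    list(split = TRUE, feature = as.integer(nd$feature),
         threshold = as.numeric(nd$threshold),
         left = revive(nd$left), right = revive(nd$right))
  }
  structure(
    list(trees = lapply(obj$trees, function(t) list(root = revive(t))),
         ntree = as.integer(obj$ntree), mtry = as.integer(obj$mtry),
         min_terminal_events = as.integer(obj$min_terminal_events),
         bootstrap = isTRUE(obj$bootstrap),
         features = as.character(unlist(obj$features)),
         n = as.integer(obj$n), nevent = as.integer(obj$nevent)),
    class = "rcd_rsf"
  )
}
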
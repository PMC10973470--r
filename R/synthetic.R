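# Seeded synthetic-data generators. They emulate the statistical structure
# the pipeline assumes — a latent per-sample cell-death activity driving
# correlated expression of planted gene-set members, a dropout-inflated
# single-cell regime with malignant labels, proportional-hazards survival
# tied to a linear risk, and a logistic response link — without modelling
# count-level noise. All generators are bit-reproducible from their seed
# and leave the caller's RNG state untouched.

synthetic_gene_ids <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

#' Synthetic cell-death gene-set collection
#'
#' Draws `n_sets` gene sets from a common planted pool inside a universe of
#' `n_genes` synthetic gene identifiers, mimicking the overlap structure of
#' curated cell-death signatures. The planted pool is what the screen is
#' later asked to recover.
#'
#' @param n_genes Size of the gene universe.
#' @param n_sets Number of sets (default 18).
#' @param set_size Genes per set.
#' @param n_planted Size of the shared planted pool the sets draw from.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] whose gene names live in the universe
#'   `sprintf("g%04d", 1:n_genes)`.
#' @export
synthetic_rcd_sets <- function(n_genes, n_sets = 18L, set_size = 12L,
                               n_planted = 50L, seed = 1L) {
  stopifnot(n_planted <= n_genes, set_size <= n_planted, n_sets >= 1L)
  genes <- synthetic_gene_ids(n_genes)
  types <- c("apoptosis", "necroptosis", "pyroptosis", "ferroptosis",
             "cuproptosis", "autophagy", "parthanatos", "entotic",
             "netotic", "lysosome_dependent", "alkaliptosis", "oxeiptosis",
             "immunogenic", "anoikis", "paraptosis", "methuosis",
             "disulfidptosis", "mpt_driven")
  types <- rep_len(types, n_sets)
  withr::with_seed(seed, {
    pool <- sort(sample(genes, n_planted))
    sets <- lapply(seq_len(n_sets), function(i) sample(pool, set_size))
  })
  names(sets) <- sprintf("RCD_%02d_%s", seq_len(n_sets), types)
  gene_set_collection(sets, rcd_type = types,
                      provenance = rep("synthetic", n_sets))
}

new_truth <- function(...) {
  structure(list(...), class = "synthetic_truth")
}

#' Generate a synthetic bulk expression matrix
#'
#' A latent activity `u_s ~ N(0, 1)` per sample drives the expression of
#' every gene belonging to `sets`: member genes get
#' `baseline + effect * u_s * beta_g + noise` with gene loadings
#' `beta_g ~ lognormal(mean 1)`; background genes are baseline plus unit
#' noise. Values are on a log-expression-like scale. With the defaults
#' (`effect = 0.75`, `noise_sd = 1`) the Spearman correlation between a
#' planted gene and the latent activity is about 0.6.
#'
#' @param n_samples,n_genes Matrix dimensions.
#' @param sets A [gene_set_collection()] referencing genes inside the
#'   universe `sprintf("g%04d", 1:n_genes)` (e.g. [synthetic_rcd_sets()]).
#' @param effect Latent-activity effect size (>= 0; 0 gives a null matrix).
#' @param noise_sd Residual noise sd of planted genes.
#' @param seed Integer seed.
#' @return A list with `expr` (genes x samples matrix) and `truth`
#'   (planted genes, latent activity `u`, loadings `beta`, seed).
#' @export
generate_bulk <- function(n_samples, n_genes, sets, effect = 0.75,
                          noise_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 2L, n_genes >= 2L, effect >= 0, noise_sd > 0)
  genes <- synthetic_gene_ids(n_genes)
  samples <- sprintf("s%04d", seq_len(n_samples))
  planted <- sort(unique(unlist(
    if (inherits(sets, "gene_set_collection")) sets$sets else sets,
    use.names = FALSE
  )))
  if (!all(planted %in% genes)) {
    stop("gene sets reference genes outside the synthetic universe",
         call. = FALSE)
  }
  pi <- match(planted, genes)
  withr::with_seed(seed, {
    u <- stats::rnorm(n_samples)
    base <- stats::runif(n_genes, 2, 8)
    mat <- base + matrix(stats::rnorm(n_genes * n_samples), n_genes)
    beta <- stats::rlnorm(length(pi), meanlog = -0.25^2 / 2, sdlog = 0.25)
    mat[pi, ] <- base[pi] +
      matrix(stats::rnorm(length(pi) * n_samples, sd = noise_sd),
             length(pi)) +
      effect * outer(beta, u)
  })
  dimnames(mat) <- list(genes, samples)
  list(expr = mat,
       truth = new_truth(planted_genes = planted,
                         u = stats::setNames(u, samples),
                         beta = stats::setNames(beta, planted),
                         seed = seed))
}

#' Generate a synthetic single-cell expression matrix
#'
#' Bulk-style latent-activity signal plus Bernoulli dropout zeros.
#' Malignant cells (a fixed fraction of cells) get `+malignant_shift` on
#' planted genes (natural-log scale) and elevated latent activity
#' (`+activity_shift` on `u`). Dropout replaces each entry by exact zero
#' independently with probability `dropout_rate`, so the expected zero
#' fraction equals `dropout_rate`.
#'
#' @inheritParams generate_bulk
#' @param n_cells Number of cells.
#' @param dropout_rate Probability an entry is zeroed (in \[0, 1)).
#' @param malignant_fraction Fraction of malignant cells (in (0, 1)).
#' @param malignant_shift Additive planted-gene shift in malignant cells.
#' @param activity_shift Latent-activity elevation of malignant cells.
#' @return A list with `expr`, `malignant` (named logical) and `truth`.
#' @export
generate_sc <- function(n_cells, n_genes, sets, effect = 0.75,
                        noise_sd = 1, dropout_rate = 0.3,
                        malignant_fraction = 0.5, malignant_shift = 0.3,
                        activity_shift = 0.5, seed = 1L) {
  stopifnot(n_cells >= 4L, n_genes >= 2L, effect >= 0, noise_sd > 0)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (malignant_fraction <= 0 || malignant_fraction >= 1) {
    stop("`malignant_fraction` must lie in (0, 1)", call. = FALSE)
  }
  genes <- synthetic_gene_ids(n_genes)
  cells <- sprintf("c%05d", seq_len(n_cells))
  planted <- sort(unique(unlist(
    if (inherits(sets, "gene_set_collection")) sets$sets else sets,
    use.names = FALSE
  )))
  if (!all(planted %in% genes)) {
    stop("gene sets reference genes outside the synthetic universe",
         call. = FALSE)
  }
  pi <- match(planted, genes)
  n_mal <- max(1L, min(n_cells - 1L, round(malignant_fraction * n_cells)))
  withr::with_seed(seed, {
    mal <- rep(FALSE, n_cells)
    mal[sample.int(n_cells, n_mal)] <- TRUE
    u <- stats::rnorm(n_cells) + activity_shift * mal
    base <- stats::runif(n_genes, 2, 6)
    mat <- base + matrix(stats::rnorm(n_genes * n_cells), n_genes)
    beta <- stats::rlnorm(length(pi), meanlog = -0.25^2 / 2, sdlog = 0.25)
    mat[pi, ] <- base[pi] +
      matrix(stats::rnorm(length(pi) * n_cells, sd = noise_sd),
             length(pi)) +
      effect * outer(beta, u) +
      malignant_shift * matrix(rep(mal, each = length(pi)), length(pi))
    if (dropout_rate > 0) {
      drop <- matrix(stats::runif(n_genes * n_cells) < dropout_rate,
                     n_genes)
      mat[drop] <- 0
    }
  })
  dimnames(mat) <- list(genes, cells)
  list(expr = mat,
       malignant = stats::setNames(mal, cells),
       truth = new_truth(planted_genes = planted,
                         u = stats::setNames(u, cells),
                         beta = stats::setNames(beta, planted),
                         seed = seed))
}

#' Generate proportional-hazards survival data
#'
#' Event times are exponential with rate `baseline_rate * exp(X beta)`;
#' censoring times are uniform on (0, `censor_horizon`) (`Inf` disables
#' censoring). Observed time is the minimum, the event indicator marks an
#' observed event.
#'
#' @param X Numeric covariate matrix, samples x features.
#' @param beta True log-hazard coefficients, one per feature.
#' @param baseline_rate Positive baseline hazard rate.
#' @param censor_horizon Upper end of the uniform censoring window.
#' @param seed Integer seed.
#' @return A [survival_data()] object carrying `X` as covariates; the true
#'   linear risk is stored in attribute `truth`.
#' @export
generate_survival <- function(X, beta, baseline_rate = 0.1,
                              censor_horizon = 20, seed = 1L) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) {
    stop("`beta` must have one coefficient per column of `X`", call. = FALSE)
  }
  if (!is.numeric(baseline_rate) || baseline_rate <= 0) {
    stop("`baseline_rate` must be positive", call. = FALSE)
  }
  if (censor_horizon <= 0) {
    stop("`censor_horizon` must be positive (use Inf for no censoring)",
         call. = FALSE)
  }
  n <- nrow(X)
  eta <- drop(X %*% beta)
  withr::with_seed(seed, {
    tt <- stats::rexp(n, rate = baseline_rate * exp(eta))
    cc <- if (is.finite(censor_horizon)) {
      stats::runif(n, 0, censor_horizon)
    } else {
      rep(Inf, n)
    }
  })
  time <- pmin(tt, cc)
  event <- as.integer(tt <= cc)
  out <- survival_data(time, event, X)
  attr(out, "truth") <- new_truth(eta = eta, beta = beta, seed = seed)
  out
}

#' Generate binary response labels linked to a score
#'
#' `label ~ Bernoulli(plogis(intercept + slope * score))`. When
#' `target_rate` is given the intercept is solved so the expected responder
#' fraction matches it (e.g. 0.28 mirrors typical checkpoint-inhibitor
#' cohorts).
#'
#' @param scores Finite numeric scores.
#' @param intercept,slope Logistic link parameters.
#' @param target_rate Optional expected positive rate overriding
#'   `intercept`.
#' @param seed Integer seed.
#' @return Integer 0/1 labels (named like `scores`); the link parameters
#'   are stored in attribute `truth`.
#' @export
generate_ici <- function(scores, intercept = 0, slope = 1,
                         target_rate = NULL, seed = 1L) {
  s <- as.numeric(scores)
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (!is.null(target_rate)) {
    stopifnot(target_rate > 0, target_rate < 1)
    intercept <- stats::uniroot(
      function(b) mean(stats::plogis(b + slope * s)) - target_rate,
      c(-50, 50)
    )$root
  }
  pr <- stats::plogis(intercept + slope * s)
  labels <- withr::with_seed(seed, stats::rbinom(length(s), 1L, pr))
  labels <- stats::setNames(as.integer(labels), names(scores))
  attr(labels, "truth") <- new_truth(intercept = intercept, slope = slope,
                                     seed = seed)
  labels
}
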
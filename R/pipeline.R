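# Pipeline orchestration: a declarative YAML configuration drives four
# stages (score, screen, survival, crispr). Every run writes a
# machine-readable manifest of its parameters; outputs are deterministic
# functions of config + seed (manifests carry no timestamps for that
# reason).

config_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("rcdsig_config_error", "error", "condition")))
}

check_keys <- function(x, allowed, section) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    config_error("unknown key(s) in '", section, "': ",
                 paste(unknown, collapse = ", "))
  }
}

need_key <- function(x, key, section) {
  if (is.null(x[[key]])) {
    config_error("missing required key '", key, "' in '", section, "'")
  }
  x[[key]]
}

need_file <- function(path, what) {
  if (!file.exists(path)) {
    config_error(what, " not found: ", path)
  }
  path
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML document with optional sections `score`,
#' `screen`, `survival` and `crispr` plus top-level `seed` and
#' `output_dir`. Unknown keys are rejected with a field-level message
#' (condition class `rcdsig_config_error`).
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    need_file(path, "config file")
    yaml::read_yaml(path)
  }
  check_keys(cfg, c("seed", "output_dir", "score", "screen", "survival",
                    "crispr"), "config")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    config_error("'seed' must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) config_error("missing required key 'output_dir'")
  if (!is.null(cfg$score)) {
    check_keys(cfg$score, c("expression", "genesets", "level", "n_sets",
                            "alpha", "normalize", "es_mode"), "score")
  }
  if (!is.null(cfg$screen)) {
    check_keys(cfg$screen,
               c("genesets", "n_sets", "bulk", "sc", "p_threshold",
                 "sc_logfc_threshold", "geo_mean_threshold_bulk",
                 "geo_mean_threshold_sc", "min_datasets", "sign_policy",
                 "adjust_p", "alpha", "normalize", "es_mode"), "screen")
    for (ds in cfg$screen$bulk) {
      check_keys(ds, c("id", "expression"), "screen.bulk[]")
    }
    for (ds in cfg$screen$sc) {
      check_keys(ds, c("id", "expression", "labels"), "screen.sc[]")
    }
  }
  if (!is.null(cfg$survival)) {
    check_keys(cfg$survival,
               c("expression", "survival", "signature", "split",
                 "prefilter_p", "ntree", "mtry", "min_terminal_events"),
               "survival")
  }
  if (!is.null(cfg$crispr)) {
    check_keys(cfg$crispr, c("cell_lines", "immune", "q", "signature"),
               "crispr")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

prepare_out <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$output_dir
}

write_manifest <- function(out_dir, stage, params) {
  jsonlite::write_json(
    list(tool = "rcdsig",
         version = as.character(utils::packageVersion("rcdsig")),
         stage = stage, params = params),
    file.path(out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

screen_config_from <- function(sc) {
  screen_config(
    p_threshold = sc$p_threshold %||% 0.05,
    sc_logfc_threshold = sc$sc_logfc_threshold %||% 0.25,
    geo_mean_threshold_bulk = sc$geo_mean_threshold_bulk %||% 0.35,
    geo_mean_threshold_sc = sc$geo_mean_threshold_sc %||% 0.2,
    min_datasets = sc$min_datasets %||% 3L,
    sign_policy = sc$sign_policy %||% "consistent-sign",
    adjust_p = sc$adjust_p %||% FALSE
  )
}

enrich_for_level <- function(expr, sets, level, opts) {
  if (level == "bulk") {
    ssgsea_scores(expr, sets, alpha = opts$alpha %||% 0.25,
                  normalize = opts$normalize %||% TRUE)
  } else {
    gsva_scores(expr, sets, es_mode = opts$es_mode %||% "diff-of-extremes")
  }
}

#' Run the scoring stage
#'
#' Computes single-sample enrichment for the configured gene sets, the
#' composite score, and the median strata; writes `enrichment.tsv`,
#' `rcd_scores.tsv`, `strata.tsv` and a manifest into `output_dir`.
#'
#' @param config Path to a YAML config or a parsed list; requires a
#'   `score` section with `expression`, `genesets` and `level`
#'   (`"bulk"` or `"sc"`).
#' @return Invisible named list of output paths.
#' @export
run_score <- function(config) {
  cfg <- read_pipeline_config(config)
  sc <- cfg$score
  if (is.null(sc)) config_error("config has no 'score' section")
  level <- need_key(sc, "level", "score")
  if (!level %in% c("bulk", "sc")) {
    config_error("'score.level' must be \"bulk\" or \"sc\"")
  }
  expr <- read_expression_any(need_file(need_key(sc, "expression", "score"),
                                        "expression input"))
  sets <- read_gmt(need_file(need_key(sc, "genesets", "score"), "GMT file"))
  out_dir <- prepare_out(cfg)
  enr <- enrich_for_level(expr, sets, level, sc)
  scores <- rcd_score(enr, n_sets = sc$n_sets %||% 18L)
  strata <- stratify_median(scores)
  paths <- c(enrichment = file.path(out_dir, "enrichment.tsv"),
             scores = file.path(out_dir, "rcd_scores.tsv"),
             strata = file.path(out_dir, "strata.tsv"))
  write_expression(as.matrix(enr), paths["enrichment"], id_col = "set_name")
  write_tsv_df(data.frame(sample_id = names(scores),
                          rcd_score = unname(scores)), paths["scores"])
  write_tsv_df(strata, paths["strata"])
  write_manifest(out_dir, "score",
                 list(level = level, n_sets = sc$n_sets %||% 18L,
                      alpha = sc$alpha %||% 0.25,
                      normalize = sc$normalize %||% TRUE,
                      es_mode = sc$es_mode %||% "diff-of-extremes",
                      seed = cfg$seed))
  invisible(as.list(paths))
}

#' Run the four-step signature screen
#'
#' Scores every configured bulk and single-cell dataset, screens each
#' against its composite score, aggregates candidates per level and
#' intersects them into the final signature. Writes per-dataset screen
#' tables, the two candidate tables, `rcd_sig.gmt` and a manifest.
#'
#' @param config Path to a YAML config or a parsed list; requires a
#'   `screen` section with `genesets`, at least one `bulk` and one `sc`
#'   dataset entry.
#' @return Invisible list with the signature and output paths.
#' @export
run_screen <- function(config) {
  cfg <- read_pipeline_config(config)
  sc <- cfg$screen
  if (is.null(sc)) config_error("config has no 'screen' section")
  if (length(sc$bulk) < 1L || length(sc$sc) < 1L) {
    config_error("'screen' needs at least one bulk and one sc dataset")
  }
  sets <- read_gmt(need_file(need_key(sc, "genesets", "screen"), "GMT file"))
  n_sets <- sc$n_sets %||% 18L
  scfg <- screen_config_from(sc)
  out_dir <- prepare_out(cfg)
  run_one <- function(ds, level, i) {
    id <- ds$id %||% paste0(level, i)
    expr <- read_expression_any(need_file(
      need_key(ds, "expression", paste0("screen.", level)), "expression"))
    enr <- enrich_for_level(expr, sets, level, sc)
    scores <- rcd_score(enr, n_sets = n_sets)
    res <- if (level == "bulk") {
      screen_dataset_bulk(expr, scores, scfg, dataset_id = id)
    } else {
      lab <- utils::read.delim(need_file(
        need_key(ds, "labels", "screen.sc"), "label file"))
      if (!all(c("sample_id", "malignant") %in% names(lab))) {
        config_error("label file needs columns sample_id, malignant")
      }
      mal <- stats::setNames(lab$malignant, lab$sample_id)[colnames(expr)]
      screen_dataset_sc(expr, scores, mal, scfg, dataset_id = id)
    }
    write_tsv_df(res, file.path(out_dir, paste0("screen_", id, ".tsv")))
    res
  }
  bulk_res <- Map(run_one, sc$bulk, "bulk", seq_along(sc$bulk))
  sc_res <- Map(run_one, sc$sc, "sc", seq_along(sc$sc))
  bulk_tab <- aggregate_candidates(bulk_res, scfg, level = "bulk")
  sc_tab <- aggregate_candidates(sc_res, scfg, level = "sc")
  sig <- derive_signature(bulk_tab, sc_tab)
  write_tsv_df(bulk_tab, file.path(out_dir, "candidates_bulk.tsv"))
  write_tsv_df(sc_tab, file.path(out_dir, "candidates_sc.tsv"))
  gmt_path <- file.path(out_dir, "rcd_sig.gmt")
  if (length(sig)) {
    write_gmt(gene_set_collection(list(RCD.Sig = sig),
                                  provenance = "derived signature"),
              gmt_path)
  } else {
    writeLines(character(0), gmt_path)
  }
  write_manifest(out_dir, "screen",
                 c(unclass(scfg), list(n_sets = n_sets, seed = cfg$seed,
                                       n_bulk = length(sc$bulk),
                                       n_sc = length(sc$sc))))
  invisible(list(signature = sig,
                 candidates_bulk = bulk_tab, candidates_sc = sc_tab,
                 gmt = gmt_path))
}

# Shared train/evaluate core used by run_survival and the acceptance
# checks: univariate prefilter on the whole cohort, stepwise Cox on the
# training split, survival forest on the selected genes, mortality risk on
# every split.
survival_pipeline <- function(d, train_idx, test_idx_list,
                              prefilter_p = 0.05, ntree = 300L,
                              mtry = NULL, min_terminal_events = 3L,
                              seed = 1L) {
  feats <- colnames(d$x)
  keep <- vapply(feats, function(f) {
    uni <- tryCatch(
      suppressWarnings(cox_fit(survival_data(d$time, d$event,
                                             d$x[, f, drop = FALSE]))),
      error = function(e) NULL
    )
    if (is.null(uni)) return(FALSE)
    z <- uni$coefficients / uni$se
    pc <- 2 * stats::pnorm(-abs(z))
    med <- stats::median(d$x[, f])
    grp <- d$x[, f] > med
    pl <- if (length(unique(grp)) == 2L) {
      logrank_test(d, ifelse(grp, "high", "low"))$p_value
    } else {
      1
    }
    is.finite(pc) && pc < prefilter_p && pl < prefilter_p
  }, TRUE)
  prefiltered <- feats[keep]
  train <- subset_survival(d, train_idx)
  selected <- character(0)
  step_fit <- NULL
  if (length(prefiltered)) {
    step_fit <- stepwise_cox(survival_data(
      train$time, train$event, train$x[, prefiltered, drop = FALSE],
      train$sample_ids
    ))
    selected <- step_fit$selected
  }
  if (length(selected) == 0L) {
    # nothing prognostic survives selection: constant (uninformative) risk
    risk <- lapply(c(list(train_idx), test_idx_list),
                   function(idx) rep(0, length(idx)))
    return(list(prefiltered = prefiltered, selected = selected,
                stepwise = step_fit, forest = NULL, risk = risk))
  }
  forest <- rsf_fit(
    survival_data(train$time, train$event,
                  train$x[, selected, drop = FALSE], train$sample_ids),
    ntree = ntree, mtry = mtry %||% ceiling(sqrt(length(selected))),
    min_terminal_events = min_terminal_events, seed = seed
  )
  risk <- lapply(c(list(train_idx), test_idx_list), function(idx) {
    rsf_predict(forest, d$x[idx, selected, drop = FALSE])
  })
  list(prefiltered = prefiltered, selected = selected, stepwise = step_fit,
       forest = forest, risk = risk)
}

#' Run the survival modelling stage
#'
#' Restricts the expression matrix to the signature genes, splits samples
#' into training and one or two testing cohorts, prefilters genes by
#' univariate Cox + log-rank screening on the whole cohort, selects genes
#' by stepwise Cox on the training split and fits the log-rank-score
#' survival forest on them. Writes the prefilter table, the stepwise
#' report, the serialized forest, per-cohort risk scores and concordance
#' indices.
#'
#' @param config Path to a YAML config or a parsed list; requires a
#'   `survival` section with `expression`, `survival` (TSV) and
#'   `signature` (GMT). Optional: `split` (fractions summing to 1,
#'   default `c(0.5, 0.3, 0.2)`), `prefilter_p`, `ntree`, `mtry`,
#'   `min_terminal_events`.
#' @return Invisible list with the fitted objects and concordance table.
#' @export
run_survival <- function(config) {
  cfg <- read_pipeline_config(config)
  sv <- cfg$survival
  if (is.null(sv)) config_error("config has no 'survival' section")
  expr <- read_expression_any(need_file(
    need_key(sv, "expression", "survival"), "expression"))
  surv <- read_survival(need_file(need_key(sv, "survival", "survival"),
                                  "survival table"))
  sig_coll <- read_gmt(need_file(need_key(sv, "signature", "survival"),
                                 "signature GMT"))
  if (length(sig_coll) == 0L) config_error("signature GMT is empty")
  sig <- unique(unlist(sig_coll$sets, use.names = FALSE))
  genes <- intersect(sig, rownames(expr))
  if (length(genes) == 0L) {
    config_error("no signature gene is present in the expression matrix")
  }
  ids <- intersect(surv$sample_ids, colnames(expr))
  if (length(ids) < 10L) {
    config_error("fewer than 10 samples shared by expression and survival")
  }
  sel <- match(ids, surv$sample_ids)
  d <- survival_data(surv$time[sel], surv$event[sel],
                     t(expr[genes, ids, drop = FALSE]), ids)
  if (sum(d$event) < 10L) config_error("too few events (need >= 10)")
  split <- unlist(sv$split %||% c(0.5, 0.3, 0.2))
  if (any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    config_error("'survival.split' fractions must be positive and sum to 1")
  }
  n <- length(ids)
  perm <- withr::with_seed(cfg$seed, sample.int(n))
  bounds <- c(0, round(cumsum(split) * n))
  bounds[length(bounds)] <- n
  cohorts <- lapply(seq_along(split), function(i) {
    sort(perm[(bounds[i] + 1L):bounds[i + 1L]])
  })
  res <- survival_pipeline(
    d, train_idx = cohorts[[1L]], test_idx_list = cohorts[-1L],
    prefilter_p = sv$prefilter_p %||% 0.05,
    ntree = sv$ntree %||% 300L, mtry = sv$mtry,
    min_terminal_events = sv$min_terminal_events %||% 3L,
    seed = cfg$seed
  )
  out_dir <- prepare_out(cfg)
  write_tsv_df(data.frame(gene = genes,
                          prefiltered = genes %in% res$prefiltered,
                          selected = genes %in% res$selected),
               file.path(out_dir, "feature_selection.tsv"))
  cohort_names <- c("train", paste0("test", seq_along(cohorts[-1L])))
  cidx <- vapply(seq_along(cohorts), function(i) {
    di <- subset_survival(d, cohorts[[i]])
    if (length(unique(res$risk[[i]])) < 2L) 0.5 else c_index(res$risk[[i]], di)
  }, 0)
  for (i in seq_along(cohorts)) {
    write_tsv_df(data.frame(sample_id = d$sample_ids[cohorts[[i]]],
                            risk = res$risk[[i]]),
                 file.path(out_dir, paste0("risk_", cohort_names[i], ".tsv")))
  }
  write_tsv_df(data.frame(cohort = cohort_names, n = lengths(cohorts),
                          c_index = cidx),
               file.path(out_dir, "c_index.tsv"))
  if (!is.null(res$forest)) {
    write_rsf_json(res$forest, file.path(out_dir, "model.json"))
  }
  write_manifest(out_dir, "survival",
                 list(seed = cfg$seed, split = split,
                      prefilter_p = sv$prefilter_p %||% 0.05,
                      ntree = sv$ntree %||% 300L,
                      n_signature_genes = length(genes),
                      selected = res$selected))
  invisible(list(selected = res$selected, stepwise = res$stepwise,
                 forest = res$forest, c_index = stats::setNames(cidx,
                                                                cohort_names),
                 cohorts = cohorts))
}

#' Run the CRISPR ranking stage
#'
#' Ranks the cell-fitness and immune-screen score matrices by per-gene mean
#' score, takes the configured lowest fraction of each, and intersects the
#' two hit sets with the signature.
#'
#' @param config Path to a YAML config or a parsed list; requires a
#'   `crispr` section with `cell_lines`, `immune` (gene x dataset TSVs) and
#'   `signature` (GMT); optional `q` (default 0.10).
#' @return Invisible list with the ranked tables, hit sets and
#'   intersection.
#' @export
run_crispr <- function(config) {
  cfg <- read_pipeline_config(config)
  cr <- cfg$crispr
  if (is.null(cr)) config_error("config has no 'crispr' section")
  q <- cr$q %||% 0.10
  cell <- mean_rank_scores(read_score_matrix(need_file(
    need_key(cr, "cell_lines", "crispr"), "cell-line score matrix")))
  immune <- mean_rank_scores(read_score_matrix(need_file(
    need_key(cr, "immune", "crispr"), "immune score matrix")))
  sig_coll <- read_gmt(need_file(need_key(cr, "signature", "crispr"),
                                 "signature GMT"))
  sig <- unique(unlist(sig_coll$sets, use.names = FALSE))
  cell_hits <- top_fraction(cell, q)
  immune_hits <- top_fraction(immune, q)
  hits <- intersect_hits(cell_hits, immune_hits, sig)
  out_dir <- prepare_out(cfg)
  write_tsv_df(cell, file.path(out_dir, "rank_cell_lines.tsv"))
  write_tsv_df(immune, file.path(out_dir, "rank_immune.tsv"))
  write_tsv_df(data.frame(gene = hits), file.path(out_dir, "hits.tsv"))
  write_manifest(out_dir, "crispr",
                 list(q = q, seed = cfg$seed,
                      n_cell_hits = length(cell_hits),
                      n_immune_hits = length(immune_hits)))
  invisible(list(cell_rank = cell, immune_rank = immune,
                 cell_hits = cell_hits, immune_hits = immune_hits,
                 hits = hits))
}

#' Write a ready-to-run synthetic input bundle
#'
#' Generates a small, fully seeded set of pipeline inputs (bulk expression
#' TSVs, a single-cell MTX triplet with labels, the gene-set GMT, a
#' survival table, CRISPR score tables) plus a `config.yaml` wired to them,
#' so every pipeline stage can be exercised end to end.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_samples,n_cells,n_genes Sizes of the generated datasets.
#' @return Invisible path of the written config file.
#' @export
write_synthetic_inputs <- function(dir, seed = 1L, n_samples = 80L,
                                   n_cells = 150L, n_genes = 120L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- synthetic_rcd_sets(n_genes, n_sets = 18L, set_size = 8L,
                             n_planted = 30L, seed = seed)
  write_gmt(sets, file.path(dir, "rcd_sets.gmt"))
  for (i in 1:2) {
    bulk <- generate_bulk(n_samples, n_genes, sets, seed = seed + i)
    write_expression(bulk$expr, file.path(dir, sprintf("bulk%d.tsv", i)))
  }
  sc <- generate_sc(n_cells, n_genes, sets, seed = seed + 10L)
  write_mtx(sc$expr, file.path(dir, "sc1"))
  write_tsv_df(data.frame(sample_id = names(sc$malignant),
                          malignant = as.integer(sc$malignant)),
               file.path(dir, "sc1_labels.tsv"))
  bulk1 <- read_expression(file.path(dir, "bulk1.tsv"))
  X <- t(bulk1[sets$sets[[1L]], , drop = FALSE])
  beta <- stats::setNames(rep(0.5, ncol(X)), colnames(X))
  surv <- generate_survival(scale(X), beta, baseline_rate = 0.15,
                            censor_horizon = 30, seed = seed + 20L)
  surv$sample_ids <- colnames(bulk1)
  write_survival(surv, file.path(dir, "survival.tsv"))
  crispr_genes <- synthetic_gene_ids(n_genes)
  cr <- withr::with_seed(seed + 30L, {
    m1 <- matrix(stats::rnorm(n_genes * 4), n_genes, 4,
                 dimnames = list(crispr_genes, paste0("cl", 1:4)))
    m2 <- matrix(stats::rnorm(n_genes * 3), n_genes, 3,
                 dimnames = list(crispr_genes, paste0("imm", 1:3)))
    list(m1, m2)
  })
  write_expression(cr[[1L]], file.path(dir, "crispr_cell_lines.tsv"))
  write_expression(cr[[2L]], file.path(dir, "crispr_immune.tsv"))
  cfg <- list(
    seed = as.integer(seed),
    output_dir = file.path(dir, "out"),
    score = list(expression = file.path(dir, "bulk1.tsv"),
                 genesets = file.path(dir, "rcd_sets.gmt"),
                 level = "bulk"),
    screen = list(
      genesets = file.path(dir, "rcd_sets.gmt"),
      min_datasets = 1L,
      bulk = list(list(id = "b1", expression = file.path(dir, "bulk1.tsv")),
                  list(id = "b2", expression = file.path(dir, "bulk2.tsv"))),
      sc = list(list(id = "s1", expression = file.path(dir, "sc1"),
                     labels = file.path(dir, "sc1_labels.tsv")))
    ),
    survival = list(expression = file.path(dir, "bulk1.tsv"),
                    survival = file.path(dir, "survival.tsv"),
                    signature = file.path(dir, "rcd_sets.gmt"),
                    split = c(0.6, 0.4), ntree = 50L),
    crispr = list(cell_lines = file.path(dir, "crispr_cell_lines.tsv"),
                  immune = file.path(dir, "crispr_immune.tsv"),
                  q = 0.10,
                  signature = file.path(dir, "rcd_sets.gmt"))
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
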
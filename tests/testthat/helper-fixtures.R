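# Small fixtures built in code.

toy_expr <- function(ng = 10, ns = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(ng * ns, mean = 5), ng, ns,
                dimnames = list(sprintf("g%02d", seq_len(ng)),
                                sprintf("s%02d", seq_len(ns))))
  })
  m
}

toy_collection <- function() {
  gene_set_collection(
    list(alpha = c("g01", "g02", "g03"),
         beta = c("g03", "g04"),
         gamma = c("g05", "g06", "g07")),
    rcd_type = c("apoptosis", "apoptosis", "ferroptosis"),
    provenance = c("src1", "src2", "src3")
  )
}

random_sets <- function(gene_ids, n_sets, seed) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(gene_ids, sample(2:(length(gene_ids) - 1), 1))
    })
  })
  names(sets) <- paste0("set", seq_len(n_sets))
  sets
}

# 18-set enrichment-like matrix for rcd_score tests
toy_enrichment18 <- function(ns = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(18 * ns), 18, ns,
                dimnames = list(sprintf("set%02d", 1:18),
                                sprintf("s%02d", seq_len(ns))))
  })
  m
}
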
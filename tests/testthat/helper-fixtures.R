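# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except the installed GMT registry.

# A small cohort with a 20-gene signature carrying a class effect.
small_cohort <- function(effect = 2, sd = 0.3, seed = 1,
                         n_genes = 200, n_sig = 20,
                         n_responders = 18, n_nonresponders = 24, ...) {
  spec <- cohort_spec(n_responders = n_responders,
                      n_nonresponders = n_nonresponders,
                      n_genes = n_genes,
                      signature_genes = sprintf("GENE%06d", seq_len(n_sig)),
                      effect_log2fc = effect, gene_sd = sd, seed = seed, ...)
  c(generate_cohort(spec), list(spec = spec))
}

signature_from_cohort <- function(cohort, name = "sig") {
  gene_signature(name, cohort$spec$signature_genes)
}

# Independent brute-force AUC oracle: count all positive/negative pairs.
auc_by_pair_counting <- function(pos, neg) {
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(wins)
}

# Independent clustering objective: plain-R loop with stats::cor, no shared
# code with the package internals.
objective_by_cor <- function(x, assign) {
  z <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  total <- 0
  for (cl in unique(assign)) {
    members <- which(assign == cl)
    centroid <- colMeans(z[members, , drop = FALSE])
    for (i in members) total <- total + (1 - cor(x[i, ], centroid))
  }
  total
}
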
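#!/usr/bin/env Rscript
# Validate every signature in the registry against the simulated cohort:
# map its genes onto the matrix, k-means cluster the 42 patients on the
# signature-restricted profiles under Pearson dissimilarity (k = 2, 100
# restarts), identify the clusters as responders / non-responders, and
# score sensitivity and specificity with non-responders as positives.
# Signatures are ranked by sensitivity + specificity.
#
# Reads results/cohort/, writes results/validation.json and
# results/signature_scores.tsv.

library(tnfsigval)

run_seed <- 20260928L

expr <- read_expression_tsv("results/cohort/expression.tsv")
metadata <- read_metadata_tsv("results/cohort/metadata.tsv")
registry <- read_gmt(placeholder_registry_path())

run <- validate_all_signatures(expr, metadata, registry,
                               cluster_config(seed = stage_seed(run_seed,
                                                                "validate")))
print(run)
write_validation_json(run, "results/validation.json")
write.table(run$table, "results/signature_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

small <- run$table$n_genes < 8
if (any(small)) {
  cat("note: signatures with < 8 genes give correlation distances too\n",
      "coarse for reliable separation; interpret their scores cautiously\n")
}
cohort <- cohort_summary(metadata)
cat(sprintf("cohort: %d (%d%%) responders, %d (%d%%) non-responders; DAS28 decrease p = %.2e\n",
            cohort$good$n, cohort$good$pct_of_cohort,
            cohort$none$n, cohort$none$pct_of_cohort,
            cohort$das28_decrease_welch$p))
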
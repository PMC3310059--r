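#!/usr/bin/env Rscript
# Simulate the study-sized cohort: 42 patients (18 EULAR good responders,
# 24 non-responders), 17881 gene-level expression summaries, DAS28
# trajectories consistent with the response labels, frequency-matched
# covariates, and control probes for QC. The genes of the bundled
# (placeholder) signature registry carry a class effect of |log2FC| = 2
# with per-gene SD 0.3 — the strong-signal scenario under which a working
# pipeline must recover every sufficiently large signature.
#
# Writes results/cohort/{expression,metadata,control_probes}.tsv + manifest.

library(tnfsigval)

run_seed <- 20260928L

registry <- read_gmt(placeholder_registry_path())
signature_genes <- unique(unlist(lapply(registry, `[[`, "genes")))

spec <- cohort_spec(n_responders = 18, n_nonresponders = 24,
                    n_genes = 17881,
                    signature_genes = signature_genes,
                    effect_log2fc = 2, gene_sd = 0.3,
                    seed = stage_seed(run_seed, "simulate"))

paths <- simulate_cohort_files(spec, "results/cohort")

md <- read_metadata_tsv(paths["metadata"])
cat(sprintf("wrote %d x %d expression matrix; %d responders / %d non-responders\n",
            spec$n_genes, nrow(md), sum(md$response == "good"),
            sum(md$response == "none")))
cat(sprintf("%d signature genes informative (|log2FC| = %g, sd = %g)\n",
            length(signature_genes), spec$effect_log2fc, spec$gene_sd))
cat("files:\n"); print(unname(paths))
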
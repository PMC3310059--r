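#!/usr/bin/env Rscript
# Array-level QC on the simulated cohort: control-probe ROC AUC against the
# 0.85 pass threshold, inter-array Pearson-correlation outlier screen, and
# a quantile-normalisation sanity check.
#
# Reads results/cohort/, writes results/qc_report.json.

library(tnfsigval)

expr <- read_expression_tsv("results/cohort/expression.tsv")
cp_tab <- read.delim("results/cohort/control_probes.tsv")
cp <- list(positive = cp_tab$intensity[cp_tab$class == "positive"],
           negative = cp_tab$intensity[cp_tab$class == "negative"])

report <- qc_report(list(cohort = cp), expr)
write_qc_json(report, "results/qc_report.json")

cat(sprintf("control-probe AUC %.3f (threshold %.2f) -> %s\n",
            report$auc$auc[1], report$thresholds$auc_min,
            if (report$auc$pass[1]) "pass" else "FAIL"))
n_out <- sum(report$correlation$outlier)
cat(sprintf("inter-array correlation: %d outlier(s) among %d arrays (cutoff %.3f)\n",
            n_out, nrow(report$correlation), attr(report$correlation, "cutoff")))

qn <- quantile_normalize(expr)
spread <- max(colMeans(qn)) - min(colMeans(qn))
cat(sprintf("quantile normalisation: column-mean spread %.2e (rank order preserved: %s)\n",
            spread, all(apply(qn, 2, rank) == apply(expr, 2, rank))))
cat("overall QC verdict:", if (report$pass) "pass" else "FAIL", "\n")
if (!report$pass) quit(status = 1)
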
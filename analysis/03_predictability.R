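#!/usr/bin/env Rscript
# Step 3: how predictable is the accuracy loss when fossils are omitted?
# Correlates extant-only per-node accuracy with (i) node age and
# (ii) sampling similarity (Fisher's exact p comparing continental
# proportions of extant vs all species in the clade), per tree, and
# compares the two predictors' strengths with a paired t-test on
# absolute correlations.
#
# Reads results/study/records.tsv (run 02_accuracy_study.R first).
# Writes results/predictability_summary.tsv.

library(fossilareas)

rec_path <- "results/study/records.tsv"
if (!file.exists(rec_path)) stop("run analysis/02_accuracy_study.R first")
records <- read.table(rec_path, header = TRUE, sep = "\t")
records <- records[records$scenario == "extant_only", ]

pred <- correlate_predictors(records)
print(pred)
cmp <- compare_predictors(pred$per_tree$rho_age, pred$per_tree$rho_sim)
cat(sprintf("paired t-test on |rho| differences: t = %.3f, p = %.4g (n = %d)\n",
            cmp$t, cmp$p_value, cmp$n))

out <- data.frame(
  statistic = c("median_rho_age", "range_rho_age_lo", "range_rho_age_hi",
                "median_rho_sim", "range_rho_sim_lo", "range_rho_sim_hi",
                "paired_t", "paired_t_p", "n_trees"),
  value = c(pred$median_rho_age, pred$range_rho_age,
            pred$median_rho_sim, pred$range_rho_sim,
            cmp$t, cmp$p_value, cmp$n)
)
write.table(out, "results/predictability_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/predictability_summary.tsv\n")
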
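#!/usr/bin/env Rscript

# Step 2 -- signal detection summaries and group-level inference.
#
# Reads the canonical trial log from step 1, applies the exclusion rule
# (participants without a positive block3 criterion), pools blocks 4 and 5
# into per-participant per-noise-level SDT summaries, and runs the group
# stack: RM-ANOVAs over noise level for accuracy, d' and criterion;
# one-tailed FDR-corrected post-hocs against the zero-noise baseline; the
# one-sample test (and JZS Bayes factor) of the baseline criterion against
# 0; the Bayesian correlation between accuracy and criterion changes; and
# the a priori power computation.

suppressPackageStartupMessages(library(srbias))

log_path <- "results/run01/trial_log.csv"
if (!file.exists(log_path)) {
  stop("run analysis/01_simulate_cohort.R first (missing ", log_path, ")")
}

res <- run_analyze(log_path, out_dir = "results/run01")

writeLines(res$report)
message("")
message("Group means by noise level:")
tab <- rbind(accuracy = colMeans(res$matrices$accuracy),
             dprime = colMeans(res$matrices$dprime),
             criterion = colMeans(res$matrices$criterion))
print(round(tab, 3))
message("")
message("Criterion post-hocs (one-tailed, FDR-corrected, with lnBF10):")
print(res$posthoc$criterion, digits = 3)
message("")
message("Wrote results/run01/sdt_summary.csv, group_results.csv, ",
        "report.txt")
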
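#!/usr/bin/env Rscript
# Step 2 - Control dynamics of a labeled cohort over 30 days.
#
# Simulates 20 replicates of a 1000-labeling-division cohort without
# training or death, overlays the mean-field oracle, and reports the two
# endpoint statistics the cohort is judged by: the labeled-neuron fraction
# (about 57%) and the mean chained divisions per lineage (about 1.7).

suppressPackageStartupMessages(library(nscdyn))
dir.create("results", showWarnings = FALSE)

rates <- default_rates()
cohort <- init_labeled_cohort(1000, default_proportions())
cat("initial cohort: "); print(cohort)

sims <- lapply(1:20, function(i) {
  simulate_cohort(cohort, rates, horizon = 30,
                  seed = derive_seed(202, "control", i))
})
write_trajectory_csv(sims, "results/02_control_trajectories.csv")

oracle <- expected_trajectory(cohort, rates, horizon = 30)
write.csv(oracle$df, "results/02_control_oracle.csv", row.names = FALSE)

frac <- sapply(sims, function(s) {
  cts <- counts_at(s, 30); 100 * cts[["n"]] / sum(cts)
})
divs <- sapply(sims, function(s) divisions_per_lineage(s$ledger))
end_n <- sapply(sims, function(s) counts_at(s, 30)[["n"]])

cat(sprintf("day-30 labeled neurons: %.1f +/- %.1f (oracle %.1f)\n",
            mean(end_n), sd(end_n), tail(oracle$df$n, 1)))
cat(sprintf("labeled-neuron fraction: %.2f%% +/- %.2f%%\n",
            mean(frac), sd(frac)))
cat(sprintf("divisions per lineage: %.3f +/- %.3f (oracle %.3f)\n",
            mean(divs), sd(divs),
            expected_divisions(cohort, rates, horizon = 30)))
cat("-> results/02_control_trajectories.csv, results/02_control_oracle.csv\n")
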
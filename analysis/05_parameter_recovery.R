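#!/usr/bin/env Rscript
# Step 5 — parameter recovery.
#
# Monte-Carlo validation of the whole measurement-to-reliability chain:
# for true ICC in {0.5, 0.75, 0.9}, 200 cohorts of 49 women x 2 observers
# are simulated, pushed through replicate readings, protocol aggregation
# and the one-way model, and the mean estimated ICC and SEM are compared
# with the generative truth. Single-cohort ICC estimates at n = 49 are
# noisy (RMSE up to ~0.1 at ICC 0.5), but the estimator is nearly
# unbiased and the SEM tracks sigma_error closely.

suppressPackageStartupMessages(library(skinfoldrel))

sweep <- sweep_recovery(icc_grid = c(0.5, 0.75, 0.9), R = 200,
                        n_subjects = 49, k_per_subject = 2, seed = 314)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(sweep, "results/tables/recovery.csv", row.names = FALSE)

print(sweep, digits = 3)
cat(sprintf("\nMax |ICC bias| = %.3f; SEM within %.1f%% of sigma_error.\n",
            max(abs(sweep$bias)), 100 * max(abs(sweep$sem_ratio - 1))))
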
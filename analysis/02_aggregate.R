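#!/usr/bin/env Rscript
# Step 2 — apply the measurement protocol.
#
# Reads the raw replicate readings, checks each observer session for
# protocol conformance (calliper range, completeness, the 7.5%
# third-reading rule) and aggregates every subject x observer x measure
# group to a single reported value: the mean of two readings or the
# median of three, at 0.1 resolution.

suppressPackageStartupMessages(library(skinfoldrel))

parsed <- read_measurements("results/data/readings.csv")
stopifnot(nrow(parsed$errors) == 0)
agg <- aggregate_sessions(parsed$readings)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(agg, "results/tables/aggregated.csv", row.names = FALSE)

cat(sprintf("Aggregated %d raw readings into %d session measurements.\n",
            nrow(parsed$readings), nrow(agg)))
cat(sprintf("Median-of-three used in %d (%.1f%%); %d non-conformant.\n",
            sum(agg$n_readings_used == 3),
            100 * mean(agg$n_readings_used == 3),
            sum(!agg$conformant)))
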
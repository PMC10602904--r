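#!/usr/bin/env Rscript
# Stage 5 -- region-averaged feature matrix.
#
# Averages channel-level coherence over the four scalp regions and
# assembles the instances x features matrix: one amplitude and one timing
# feature per region x bin, rows sorted by (group, participant, condition).

library(flowcoh)
run <- readRDS("scratch/run/cohort.rds")
coh <- readRDS("scratch/run/coherence.rds")
dir.create("results", showWarnings = FALSE)

keys <- paste(run$cohort$meta$participant, run$cohort$meta$condition,
              sep = "_")
specs <- lapply(keys, function(k) {
  region_average(coh[paste(coh$participant, coh$condition,
                           sep = "_") == k, ])
})
fm <- assemble(specs, run$cohort$meta)
write_feature_matrix(fm, "scratch/run/feature_matrix.csv")
saveRDS(fm, "scratch/run/feature_matrix.rds")

shape <- data.frame(instances = nrow(fm$values),
                    features = ncol(fm$values),
                    regions = 4, bins = 62, parameter_types = 2)
write.csv(shape, "results/feature_matrix_shape.csv", row.names = FALSE)

fmz <- zscale(fm)
cat(sprintf("feature matrix: %d instances x %d features\n",
            nrow(fm$values), ncol(fm$values)))
cat(sprintf("after z-scaling: max |column mean| = %.2e, max |sd - 1| = %.2e\n",
            max(abs(colMeans(fmz$values))),
            max(abs(apply(fmz$values, 2, sd) - 1))))
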
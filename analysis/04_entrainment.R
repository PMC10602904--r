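#!/usr/bin/env Rscript
# Stage 4 -- stimulus-brain coherence spectra.
#
# For every instance: narrowband-filter the continuous preprocessed EEG and
# the video's flow series at each of the 62 bins (0.2-12.4 Hz), correlate
# across 0-1000 ms lags, extract peak amplitude and peak lag, average over
# trials. Also runs a short parameter-recovery experiment showing the
# embedded cells are found again.

library(flowcoh)
run <- readRDS("scratch/run/cohort.rds")
dir.create("results", showWarnings = FALSE)

coh <- cohort_coherence(run$cohort, frequency_grid(), progress = TRUE)
saveRDS(coh, "scratch/run/coherence.rds")

# condition contrast at the embedded low-frequency bins, per region
map <- region_map()
coh$region <- NA
for (r in names(map)) coh$region[coh$channel %in% map[[r]]] <- r
sub <- coh[!is.na(coh$region) & coh$bin_center_hz %in% c(1.0, 1.2), ]
contrast <- aggregate(peak_amplitude ~ group + condition + region +
                        bin_center_hz, sub, mean)
write.csv(contrast, "results/coherence_embedded_bins.csv",
          row.names = FALSE)

rec <- recovery_experiment(n_runs = 20, n_trials = 20,
                           seed = 20260916L)
write.csv(rec, "results/recovery_runs.csv", row.names = FALSE)

cat("mean peak amplitude at the embedded bins (direct vs reversed):\n")
print(reshape(contrast, direction = "wide",
              idvar = c("group", "region", "bin_center_hz"),
              timevar = "condition"), row.names = FALSE)
cat(sprintf("\nrecovery over 20 runs: bin exact %.0f%%, lag median |err| %.1f ms\n",
            100 * mean(rec$bin_exact), median(abs(rec$lag_err_ms))))
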
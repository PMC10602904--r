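#!/usr/bin/env Rscript
# Stage 6 -- information-based feature ranking.
#
# Ranks the 496 features by mutual information with the task labels for
# each task dataset (per-group condition, combined four-class, direct-only
# group), and by the unsupervised leave-one-out dataset-entropy scorer on
# the combined data. Writes top-4 salience tables.

library(flowcoh)
fm <- readRDS("scratch/run/feature_matrix.rds")
dir.create("results", showWarnings = FALSE)

fmz <- zscale(fm)
tops <- list()
for (tk in c("group_a_condition", "group_b_condition", "four_class",
             "direct_only_group")) {
  ts <- task_spec(tk)
  rows <- which(ts$select(fmz$instances))
  rk <- ufs_rank(fmz$values[rows, , drop = FALSE],
                 labels = ts$labels(fmz$instances[rows, , drop = FALSE]))
  write_ranking_csv(rk, sprintf("results/ufs_%s.csv", tk))
  top <- rk$top
  top$task <- tk
  tops[[tk]] <- top
  cat(sprintf("\ntask %s -- top 4 features:\n", tk))
  print(top[, c("rank", "region", "parameter", "bin_center_hz", "score")],
        row.names = FALSE)
}
write.csv(do.call(rbind, tops), "results/ufs_top4.csv", row.names = FALSE)

rk_loo <- ufs_rank(fmz$values, method = "loo_entropy")
write_ranking_csv(rk_loo, "results/ufs_loo_entropy_combined.csv")
cat("\nunsupervised leave-one-out entropy -- top 4:\n")
print(rk_loo$top[, c("rank", "region", "parameter", "bin_center_hz")],
      row.names = FALSE)
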
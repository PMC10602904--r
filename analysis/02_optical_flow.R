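#!/usr/bin/env Rscript
# Stage 2 -- optical flow sanity checks on rendered videos.
#
# Renders short videos of a moving ellipse, extracts dense optical flow
# with the default global-smoothness estimator and the local least-squares
# alternative, and reports (a) monotonicity of the global flow magnitude in
# true object speed and (b) cross-algorithm agreement of the extracted
# timeseries. The global magnitude series of these videos is what stands
# in for the stimulus signal throughout.

library(flowcoh)
dir.create("results", showWarnings = FALSE)

speeds <- c(0, 1, 2, 4)
rows <- lapply(speeds, function(s) {
  v <- make_video(duration_s = 1, frame_rate_hz = 15,
                  trajectory = "constant", speed_px = s)
  hs <- global_flow(compute_flow(v$frames, method = "hs"), 15)
  lk <- global_flow(compute_flow(v$frames, method = "lk"), 15)
  data.frame(speed_px_frame = s,
             mean_global_flow_hs = mean(hs$values),
             mean_global_flow_lk = mean(lk$values))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/flow_speed_response.csv", row.names = FALSE)

v <- make_video(duration_s = 4, frame_rate_hz = 15,
                trajectory = "bandlimited", seed = 7)
hs <- global_flow(compute_flow(v$frames, method = "hs"), 15, "demo")
lk <- global_flow(compute_flow(v$frames, method = "lk"), 15, "demo")
agree <- cor(hs$values, lk$values)
write.csv(data.frame(algorithms = "hs_vs_lk", pearson_r = agree),
          "results/flow_algorithm_agreement.csv", row.names = FALSE)
write_flow_csv(hs, "results/flow_demo_video.csv")

cat("mean global flow by true speed (px/frame):\n")
print(tab, row.names = FALSE)
cat(sprintf("cross-algorithm agreement on a band-limited trajectory: r = %.3f\n",
            agree))
cat(sprintf("monotone in speed: %s\n",
            all(diff(tab$mean_global_flow_hs) > 0)))
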
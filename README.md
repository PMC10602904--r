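# flowcoh

Frequency-resolved coherence between a video stimulus and multichannel EEG,
with feature ranking and brain-state classification on top.

## The problem

When people watch a video of human motion — sign language being the extreme
case, where the motion *is* the message — their cortical activity tracks the
stimulus's motion energy. Two questions follow: **at which frequencies and
scalp regions** does the brain entrain to the stimulus, **and with what
delay**; and do those entrainment signatures differ between populations
(e.g., fluent signers vs. non-signers) and conditions (a video played
forward vs. time-reversed, which preserves low-level visual statistics but
destroys comprehensibility)? flowcoh is a tested, reproducible
implementation of the full analysis chain for these questions, aimed at EEG
researchers studying neural entrainment to naturalistic visual stimuli.

## The method

1. **Stimulus signal** — dense optical flow between adjacent frames
   (Horn–Schunck by default); per-pixel velocity magnitudes are summed per
   frame transition into the global flow timeseries `s(t)`.
2. **EEG preprocessing** — mastoid re-referencing, 0.1–30 Hz zero-phase
   Butterworth (48 dB/oct, cascaded second-order sections), regression-based
   ocular correction with propagation factors `b_H, b_V` estimated by least
   squares, 0–5 s epochs from stimulus onsets, ±75 µV amplitude rejection.
3. **Coherence** — for every bin `f` of a 0.2–12.4 Hz grid (62 bins, 0.2 Hz
   apart), both `s(t)` (resampled to the EEG rate) and each channel `y(t)`
   are narrowband-filtered at `f` (second-order IIR, 0.2 Hz bandwidth,
   forward–backward); the coherence amplitude is
   `max_tau | corr( s_f(t), y_f(t + tau) ) |` over lags `tau` in 0–1000 ms,
   and the coherence timepoint is the argmax. Trials are aggregated by
   averaging the correlation profiles `r(tau)` before peak-picking.
4. **Features** — channel-level peaks averaged over four scalp regions
   (anterior, posterior, left, right; five 10/20 electrodes each):
   4 regions × 62 bins × {amplitude, time} = 496 features per instance
   (participant × condition); columns z-scaled, fit on training rows only.
5. **Ranking** — univariate information scores: mutual information
   `I(feature; label)` in bits under equal-frequency discretisation, or an
   unsupervised leave-one-out dataset-entropy score.
6. **Classification** — ten algorithms (LR, LDA, kNN, CART, NB, SVM, and
   ensembles RF/100, ET/100, AdaBoost/50, GBM/100) under 10-fold
   participant-grouped cross-validation with fold-local scaling and a 20%
   per-group participant hold-out.

A synthetic-data module generates videos, flow signals, and EEG with *known*
embedded entrainment cells (region × frequency × lag × snr), so every stage
is verified by parameter recovery; see the methods vignette
(`vignettes/methods.Rmd`) for the generative model and estimator choices.

## Worked example

Embed one entrainment cell — left hemisphere, 1.0 Hz, 200 ms lag, snr 6 —
in a synthetic participant, and recover it:

```r
library(flowcoh)

cell <- data.frame(group = "a", region = "left",
                   frequency_hz = 1.0, lag_ms = 200, snr = 6)
spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                   n_videos_per_condition = 6, eeg_rate_hz = 250,
                   entrainment_cells = cell, seed = 7)

flows <- lapply(1:6, function(i)
  synth_flow(5.5, 30, seed = derive_seed(7, paste("flow", i)),
             source_id = sprintf("vid%02d", i)))
names(flows) <- sprintf("vid%02d", 1:6)

rec  <- make_eeg(spec, flows, "p01", group = "a", condition = "direct")
prep <- preprocess_continuous(rec)       # re-reference, band-pass, ocular
sp   <- instance_spectrum(prep, flows, aggregate = "profile_mean")

ra   <- region_average(sp)               # mean over each region's channels
left <- subset(ra, region == "left")
best <- left[which.max(left$peak_amplitude), ]
print(best[, c("region", "bin_center_hz", "peak_amplitude", "peak_time_ms")])
```

```
    region bin_center_hz peak_amplitude peak_time_ms
129   left             1      0.8825204          192
```

The argmax over the 62-bin left-region spectrum lands exactly on the
embedded 1.0 Hz bin, with a trial-averaged peak correlation of 0.88 at a
192 ms lag — 8 ms from the embedded 200 ms, which is the expected
carrier-phase precision of narrowband lag estimates (see the vignette).
Off-peak bins in the same region average ~0.27 after six-trial profile
averaging.

The `analysis/` directory holds the numbered drivers for the full study
geometry (simulate cohort → optical flow → preprocessing → coherence →
feature matrix → ranking → classification); each writes its tables under
`results/`.

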
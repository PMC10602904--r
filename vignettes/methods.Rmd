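---
title: "Stimulus-brain coherence: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-brain coherence: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

flowcoh quantifies how strongly, and at what delay, multichannel EEG tracks
the motion energy of a video stimulus. The stimulus side is the global
optical-flow magnitude timeseries: per-pixel velocity magnitudes between
adjacent frames, summed per frame transition. Both the flow series and each
EEG channel are filtered through a bank of narrow (0.2 Hz wide) second-order
IIR band-passes with centres from 0.2 to 12.4 Hz in 0.2 Hz steps (62 bins),
applied forward-backward so lags stay interpretable. Per bin and channel the
coherence is the maximal-magnitude lagged Pearson correlation over a 0-1000 ms
positive-lag window (brain follows stimulus), and the coherence timepoint is
the lag of that peak. Channel-level peaks are averaged over four scalp
regions (anterior, posterior, left, right; five 10/20 electrodes each),
yielding per instance (participant x condition) a feature vector of
4 x 62 amplitudes plus 4 x 62 timings = 496 features. Features are ranked by
information-based univariate selection, and brain states (group x condition)
are classified by a ten-member battery under a leakage-free grouped
cross-validation harness.

## Generative model behind the synthetic cohort

No public recordings accompany the design this package implements, so every
stage is validated by parameter recovery on synthetic data whose generative
structure mirrors the analysis assumptions:

- **Stimulus flow**: a band-limited (< 12 Hz), non-negative random series at
  30 frames/s emulating the motion energy of a moving articulator. Videos
  last 5-7 s; the reversed condition uses the time-reversed series of the
  same video.
- **EEG**: per channel, 1/f background noise (spectral slope 1, RMS
  8 microvolts — typical resting-EEG scale, and comfortably inside the
  +/-75 microvolt artifact bound so single-trial instances are not lost to
  rejection) plus, for each entrainment cell applicable to the participant's
  group and the channel's region, a copy of the flow resampled to the EEG
  rate, band-passed at the cell's frequency (0.2 Hz bandwidth), delayed by
  the cell's lag, and scaled so its RMS is `snr` times the channel's
  *in-band* noise RMS.
- **Populations**: group a (n = 24) carries ~1 Hz entrainment over anterior,
  posterior and left regions, 1.2 Hz on the right, and a weaker anterior
  alpha (9.4 Hz) component; group b (n = 20) lacks the alpha cell and has a
  weaker left-hemisphere cell. Reversal attenuates every cell's snr by a
  group-specific factor (0.3 for group a, 0.5 for group b). Both factors are
  modelling choices: the comprehending group loses most of its entrainment
  when the stimulus becomes incomprehensible, while the control group —
  tracking biological motion rather than language — loses less, yet enough
  that both within-group condition classifications are solvable.
- **Auxiliary channels**: two mastoids, and two bipolar EOG pairs carrying
  blink and saccade trains with known propagation factors into every scalp
  channel, so the regression-based ocular correction can be verified against
  ground truth.

Everything derives from one master seed (`derive_seed(seed, stage)` per
stage), so cohorts are bit-reproducible.

What the generator does *not* emulate: volume-conduction correlations
between channels, non-stationary artifacts (electrode drift, muscle),
between-participant variability in entrainment topography, and any actual
linguistic structure in the stimulus. Passing tests therefore demonstrate
that the pipeline recovers what it assumes, not that real sign-language EEG
behaves this way.

## Key estimator choices

**Narrowband filtering uses the continuous record.** A filter with 0.2 Hz
bandwidth rings for roughly `1/bandwidth = 5` s. Filtering a bare 5 s epoch
leaves it dominated by edge transients — in our experiments this alone
destroyed parameter recovery. The package therefore applies the filter bank
to the continuous preprocessed recording and the full-length flow series and
restricts only the *correlation window* to the epoch, the same principle
that places the broadband band-pass before epoching. Where post-stimulus
context exists, the correlation keeps a full-length window at every lag
(the response window slides instead of shrinking).

**Trial aggregation averages correlation profiles, not peaks.** With
bandwidth x duration of order 1, two independent narrowband series correlate
spuriously at ~0.7-0.9 at *some* lag in the search window, so per-trial peak
amplitudes are saturated and their mean barely separates entrained from
noise bins. Averaging the correlation profiles `r(tau)` over trials first
and then peak-picking collapses the null (independent phasors cancel as
`1/sqrt(n_trials)`) while the entrained component, locked to a common lag,
survives. The default instance-level estimator is therefore the profile
mean; the mean and median of per-trial peaks remain available
(`cohort_coherence(aggregate = )`) for per-trial statistics.

**What lag precision is attainable.** With both synthesis and analysis
band-limited to 0.2 Hz, the correlation profile is a carrier at the bin
frequency under an envelope that varies on the `1/bandwidth` (5 s) scale.
The lag is therefore identified essentially up to carrier phase: measured
precision at 1 Hz is an unbiased ~6-8 ms standard deviation with 20-trial
profile averaging (and cycle ambiguity enters above ~2 Hz where several
carrier periods fit the window). Bin localisation, by contrast, is
essentially error-free at snr >= 5. Downstream analyses should treat timing
features as informative but noisy; sample-exact lag recovery at 500 Hz is
not achievable with narrowband correlation on 5 s epochs, and the package's
recovery experiment (`recovery_experiment()`) reports the measured rates
rather than pretending otherwise.

**Lagged-correlation contract.** The per-lag Pearson correlation is computed
over the valid overlap with cumulative sums plus one FFT cross-correlation
(`O(n log n)` per pair). Zero-variance inputs yield amplitude 0 with the lag
flagged missing. Bins whose window holds fewer than two cycles of the centre
frequency (0.2-0.4 Hz on 5 s epochs) are flagged low-confidence but
retained, since low-frequency features are the scientifically interesting
ones.

**CCA reading.** The coherence of the original design ran canonical
correlation on two univariate narrowband series; for such pairs the CCA
optimum over delay embeddings coincides with the maximal lagged Pearson
correlation, which is the implemented estimator. A delay-embedded CCA mode
(`cca_correlation()`, default 32 lags) is kept as a sensitivity cross-check.

## Preprocessing parameters

| step | parameter | default | why |
|------|-----------|---------|-----|
| re-reference | mastoid labels | M1, M2 | average-of-mastoids reference |
| band-pass | cutoffs | 0.1-30 Hz | analysis band with margin |
| band-pass | roll-off | 48 dB/oct (8th order) | cascaded second-order sections, zero-phase |
| ocular | variant | whole-recording least squares | single-trial coherence is the target, not ERPs |
| epochs | window | 0-5 s from onset | shortest stimulus duration |
| rejection | bound | +/-75 microvolts | amplitude criterion only; gradient/flatline checks deliberately omitted |

The 48 dB/oct specification maps to an 8th-order Butterworth at
6 dB/oct/pole; it is designed directly in second-order sections (per-pole-pair
bilinear transform), because the expanded polynomial is numerically
ill-conditioned with a 0.1 Hz edge at 500 Hz. Rejected trials are flagged,
never dropped, and excluded from coherence aggregation; participants with no
usable trials stop the pipeline with an explicit error rather than
propagating missing cells.

## Feature matrix and harness

Columns follow a fixed, versioned order (amplitude block then time block;
regions anterior < posterior < left < right, bins ascending) so ranked
feature indices are comparable across runs. Scaling to zero mean / unit SD
is fit on training rows only wherever a train/test split exists: inside
every cross-validation fold, and once on the training set for the hold-out.
Global scaling is used only for descriptive rankings.

Folds are grouped by participant (both condition rows travel together) and
stratified by group; a class missing from any fold's training split raises
an error instead of degrading silently. The hold-out retains 20% of each
group's participants (rounded), selected by seed, and is scored once by
models refit on all training rows.

Timing features are averaged as plain means (lags are durations, not
phases, so circular statistics would be wrong).

The ten classifiers: logistic regression (the linear-regression slot of a
classification battery is read as logistic regression, the standard usage),
LDA, kNN (k = 5), CART, Gaussian naive Bayes, RBF-SVM (unit cost), random
forest (100 trees), extremely randomised trees (100 trees), AdaBoost (SAMME
over 50 depth-1 stumps), and gradient boosting (100 rounds, depth 3,
learning rate 0.1). Every stochastic component derives its seed from the
report's top-level seed, and the two libraries that touch R's global RNG
(kNN tie-breaking, ranger) are pinned so reports are bit-reproducible.

## Feature ranking

Two scorers bracket the plausible readings of information-based univariate
selection. The supervised default scores `I(discretised feature; label)` in
bits under equal-frequency discretisation with `ceiling(sqrt(n))` bins
(~9 bins at n = 88; a feature with at most that many distinct values keeps
them as-is, so a label copy scores exactly `H(label)`). The unsupervised
leave-one-out scorer reproduces the dataset-entropy reading: a feature's
score is the change in total dataset entropy when it is removed, with the
joint entropy approximated to second order as
`sum_i H(X_i) - sum_{i<j} I(X_i; X_j)` — a deliberate, documented estimator
(the exact joint entropy of 496 discretised columns is not estimable at
n = 88). Ties break deterministically: lower bin, region order, amplitude
before time.

## Problem sizes used in validation

The validation suite runs the full study geometry — 24 + 20 participants x
2 conditions, the 62-bin grid, all four regions — with the per-instance
signal load reduced to desk scale: a 100 Hz analysis rate (Nyquist still
4x the top bin) and 1-4 stimulus videos per condition instead of the study's
40, since per-trial snr rather than trial count governs every property under
test. The parameter-recovery experiment runs 100 seeded single-participant
runs at the full 500 Hz with 20 trials each. The analysis drivers under
`analysis/` run the generator defaults (500 Hz, 2 videos per condition).

## Known limitations

- Absolute peak-lag estimates are carrier-phase limited (see above); the
  timing features carry ~5-10 ms noise at low frequencies and cycle
  ambiguity at high ones.
- Single-trial coherence amplitudes are saturated by the
  bandwidth x duration ~ 1 regime; amplitude features become informative
  through trial aggregation, exactly as in the emulated study design (40
  trials per condition).
- The leave-one-out entropy scorer inherits the upward bias of discrete MI
  estimates at small n; its rankings are comparable within a dataset, not
  across sample sizes.
- The Horn-Schunck flow estimator underestimates large displacements
  (aperture and linearisation); the monotonicity of the global magnitude in
  object speed, not its absolute calibration, is what the pipeline relies
  on.
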
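# Synthetic cohort generator: determinism, spectral contract, video ground
# truth, cohort bookkeeping.

test_that("spec validation enforces the documented invariants", {
  expect_error(synth_spec(n_group_a = 0), "positive")
  expect_error(synth_spec(video_duration_s = c(3, 6)), "\\[5, 7\\]")
  expect_error(synth_spec(entrainment_cells = data.frame(
    group = "a", region = "left", frequency_hz = 15, lag_ms = 100,
    snr = 5)), "0.2, 12.4")
  expect_error(synth_spec(entrainment_cells = data.frame(
    group = "a", region = "occipital", frequency_hz = 1, lag_ms = 100,
    snr = 5)), "region")
  expect_error(synth_spec(entrainment_cells = data.frame(
    group = "a", region = "left", frequency_hz = 1, lag_ms = 100,
    snr = -1)), "snr")
})

test_that("identical seeds give bit-identical recordings and flows", {
  spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                     n_videos_per_condition = 1, eeg_rate_hz = 250,
                     seed = 9)
  fl <- synth_flow(5, 30, seed = 3, source_id = "vid01")
  fl2 <- synth_flow(5, 30, seed = 3, source_id = "vid01")
  expect_identical(fl$values, fl2$values)
  r1 <- make_eeg(spec, fl, "p01", "a", "direct")
  r2 <- make_eeg(spec, fl, "p01", "a", "direct")
  expect_identical(r1$data, r2$data)
  # different seed changes the data
  spec2 <- synth_spec(n_group_a = 1, n_group_b = 1,
                      n_videos_per_condition = 1, eeg_rate_hz = 250,
                      seed = 10)
  r3 <- make_eeg(spec2, fl, "p01", "a", "direct")
  expect_false(identical(r1$data, r3$data))
})

test_that("noise-only channels have the contracted 1/f spectral slope", {
  fs <- 250
  x <- withr::with_seed(5, one_over_f_noise(fs * 120, fs, exponent = 1))
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 31,
                          plot = FALSE, taper = 0)
  keep <- sp$freq >= 1 & sp$freq <= 10
  slope <- stats::coef(stats::lm(log(sp$spec[keep]) ~
                                   log(sp$freq[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("synthetic video ground truth matches the requested trajectory", {
  # stationary: zero displacement
  v0 <- make_video(duration_s = 1, frame_rate_hz = 10,
                   trajectory = "stationary")
  expect_equal(v0$truth, rep(0, 9))
  # constant velocity: exactly 1 px/frame
  v1 <- make_video(duration_s = 1, frame_rate_hz = 10,
                   trajectory = "constant", speed_px = 1)
  expect_equal(v1$truth, rep(1, 9), tolerance = 1e-12)
  # sinusoid at 1 Hz dominates the displacement spectrum
  v2 <- make_video(duration_s = 5, frame_rate_hz = 30,
                   trajectory = "sinusoid", osc_freq_hz = 1,
                   osc_amp_px = 8)
  sp <- Mod(stats::fft(v2$truth - mean(v2$truth)))
  freqs <- seq(0, 30, length.out = length(v2$truth) + 1)[
    seq_along(v2$truth)]
  half <- freqs > 0 & freqs < 15
  # displacement magnitude of a sinusoidal trajectory oscillates at 2f
  expect_equal(freqs[half][which.max(sp[half])], 2, tolerance = 0.15)
  expect_error(make_video(duration_s = 0), "zero frames")
})

test_that("entrainment injection requires a mappable region", {
  spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                     channel_labels = c("Fz", "Cz"),  # no left channels
                     entrainment_cells = data.frame(
                       group = "a", region = "left", frequency_hz = 1,
                       lag_ms = 100, snr = 5),
                     eeg_rate_hz = 250, seed = 1)
  fl <- synth_flow(5, 30, seed = 1)
  expect_error(make_eeg(spec, fl, "p01", "a", "direct"), "left")
})

test_that("snr = 0 produces channels uncorrelated with the stimulus", {
  spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                     n_videos_per_condition = 1,
                     entrainment_cells = data.frame(
                       group = "a", region = "left", frequency_hz = 1,
                       lag_ms = 100, snr = 0),
                     eeg_rate_hz = 250, eog = list(enable = FALSE),
                     seed = 4)
  fl <- synth_flow(5.5, 30, seed = 2, source_id = "v")
  rec <- make_eeg(spec, fl, "p01", "a", "direct")
  prep <- bandpass(rec)
  cs <- instance_spectrum(prep, list(v = fl),
                          grid = frequency_grid(0.6, 3.0, 0.6),
                          aggregate = "profile_mean")
  # single-trial profile peaks of pure noise stay saturated individually,
  # but no bin should approach a coherent peak of ~1
  expect_lt(max(cs$peak_amplitude), 0.98)
})

test_that("cohort bookkeeping matches the study design", {
  spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                     n_videos_per_condition = 2, eeg_rate_hz = 250,
                     seed = 2)
  cohort <- make_cohort(spec)
  expect_equal(nrow(cohort$meta), 4)           # 2 participants x 2 conditions
  expect_length(cohort$recordings, 4)
  # reversed flow is the exact reverse of the direct flow, per video
  for (vid in names(cohort$flows$direct)) {
    expect_identical(cohort$flows$reversed[[vid]]$values,
                     rev(cohort$flows$direct[[vid]]$values))
  }
  # every recording has one event per video
  expect_true(all(vapply(cohort$recordings,
                         function(r) nrow(r$events), integer(1)) == 2))
  # default sizes: (24 + 20) x 2 = 88 instances (bookkeeping only)
  sp <- synth_spec()
  expect_equal((sp$n_group_a + sp$n_group_b) * 2L, 88L)
})
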
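# Narrowband coherence: resampling, lagged correlation, spectra, and
# invariances.

test_that("flow resampling is band-limited interpolation", {
  # constant series stays constant
  fl <- flow_timeseries(rep(2, 150), 30)
  expect_equal(resample_flow(fl, 500)$values, rep(2, 2500),
               tolerance = 1e-6)
  # 1 Hz sinusoid at 30 fps -> 1 Hz sinusoid at 500 Hz within 1%
  t30 <- (0:299) / 30
  fl2 <- flow_timeseries(1 + 0.5 * sin(2 * pi * t30), 30)
  up <- resample_flow(fl2, 500)
  t500 <- (seq_along(up$values) - 1) / 500
  ref <- 1 + 0.5 * sin(2 * pi * t500)
  core <- 200:(length(up$values) - 200)
  expect_lt(max(abs(up$values[core] - ref[core])), 0.01)
  # round-trip 30 -> 500 -> 30 on a band-limited series
  fl3 <- synth_flow(6, 30, seed = 4)
  rt <- resample_flow(resample_flow(fl3, 500), 30)
  nmin <- min(length(rt$values), length(fl3$values))
  core <- 30:(nmin - 30)
  err <- max(abs(rt$values[core] - fl3$values[core]))
  expect_lt(err, 0.01 * diff(range(fl3$values)))
  expect_error(resample_flow(flow_timeseries(1, 30), 20), "2 x 12.4")
})

test_that("lagged correlation recovers exact delayed copies", {
  fs <- 500
  x <- withr::with_seed(2, stats::rnorm(2500))
  y <- c(rep(0, 100), x)[1:2500]
  pk <- lagged_correlation(x, y, fs)
  expect_equal(pk$peak_amplitude, 1, tolerance = 1e-6)
  expect_equal(pk$peak_time_ms, 200)
  expect_equal(pk$sign, 1)
  # anticorrelated copy: |r| ~ 1, negative sign
  y2 <- c(rep(0, 50), -x)[1:2500]
  pk2 <- lagged_correlation(x, y2, fs)
  expect_equal(pk2$peak_amplitude, 1, tolerance = 1e-6)
  expect_equal(pk2$peak_time_ms, 100)
  expect_equal(pk2$sign, -1)
  # continuous context: y longer than x keeps full overlap
  ylong <- c(rep(0, 100), x, withr::with_seed(3, stats::rnorm(600)))
  pk3 <- lagged_correlation(x, ylong, fs)
  expect_equal(pk3$peak_amplitude, 1, tolerance = 1e-6)
  expect_equal(pk3$peak_time_ms, 200)
})

test_that("per-lag Pearson matches a brute-force loop", {
  fs <- 100
  x <- withr::with_seed(5, stats::rnorm(300))
  y <- withr::with_seed(6, stats::rnorm(360))
  pk <- lagged_correlation(x, y, fs, lag_window_ms = c(0, 500),
                           return_profile = TRUE)
  taus <- 0:50
  oracle <- vapply(taus, function(tau) {
    m <- min(300, 360 - tau)
    stats::cor(x[1:m], y[(tau + 1):(tau + m)])
  }, numeric(1))
  expect_equal(pk$r, oracle, tolerance = 1e-10)
})

test_that("independent noise stays below the circular-shift null", {
  fs <- 250
  nb <- narrowband_design(2, 0.2, fs)
  x <- zero_phase(nb, withr::with_seed(7, stats::rnorm(1250)))
  y <- zero_phase(nb, withr::with_seed(8, stats::rnorm(1250)))
  obs <- lagged_correlation(x, y, fs, c(0, 500))$peak_amplitude
  null <- withr::with_seed(9, vapply(1:200, function(i) {
    shift <- sample(200:1000, 1)
    ys <- c(y[-seq_len(shift)], y[seq_len(shift)])
    lagged_correlation(x, ys, fs, c(0, 500))$peak_amplitude
  }, numeric(1)))
  expect_lt(obs, stats::quantile(null, 0.95) + 0.1)
})

test_that("zero-variance input is flagged missing, not fabricated", {
  pk <- lagged_correlation(rep(1, 500), stats::rnorm(500), 250)
  expect_equal(pk$peak_amplitude, 0)
  expect_true(is.na(pk$peak_time_ms))
})

test_that("amplitude is invariant to scaling and offsets of either signal", {
  fs <- 250
  cohort <- small_cohort()
  fl <- cohort$flows$direct[[1]]
  x <- withr::with_seed(1, stats::rnorm(1000))
  y <- withr::with_seed(2, stats::rnorm(1000)) + 0.3 * x
  base <- lagged_correlation(x, y, fs)
  for (tf in list(function(v) 3.7 * v, function(v) v + 11)) {
    pk <- lagged_correlation(tf(x), y, fs)
    expect_equal(pk$peak_amplitude, base$peak_amplitude, tolerance = 1e-9)
    expect_equal(pk$peak_time_ms, base$peak_time_ms)
    pk2 <- lagged_correlation(x, tf(y), fs)
    expect_equal(pk2$peak_amplitude, base$peak_amplitude,
                 tolerance = 1e-9)
  }
})

test_that("the default grid has exactly 62 strictly increasing bins", {
  g <- frequency_grid()
  expect_length(g$centers, 62)
  expect_equal(g$centers[1], 0.2)
  expect_equal(g$centers[62], 12.4)
  expect_true(all(diff(g$centers) > 0))
  expect_equal(unique(round(diff(g$centers), 10)), 0.2)
})

test_that("coherence spectrum localises an embedded cell", {
  fs <- 500
  cell <- data.frame(group = "a", region = "left", frequency_hz = 1.0,
                     lag_ms = 200, snr = 10)
  spec <- synth_spec(n_group_a = 1, n_group_b = 1,
                     n_videos_per_condition = 6,
                     entrainment_cells = cell,
                     channel_labels = c("C3", "Fz"),
                     eog = list(enable = FALSE), seed = 21)
  flows <- lapply(1:6, function(i) {
    synth_flow(6, 30, seed = derive_seed(21, paste("f", i)),
               source_id = sprintf("vid%02d", i))
  })
  names(flows) <- sprintf("vid%02d", 1:6)
  rec <- make_eeg(spec, flows, "p01", "a", "direct")
  prep <- bandpass(rec)
  grid <- frequency_grid(0.4, 2.4, 0.2)
  sp <- instance_spectrum(prep, flows, grid = grid,
                          aggregate = "profile_mean")
  left <- sp[sp$channel == "C3", ]
  # embedded bin wins on amplitude, lag lands near the embedded 200 ms
  expect_equal(left$bin_center_hz[which.max(left$peak_amplitude)], 1.0)
  lag_at_bin <- left$peak_time_ms[left$bin_center_hz == 1.0]
  expect_lt(abs(lag_at_bin - 200), 25)
  # channel outside the region shows no comparable peak at the cell bin
  fz <- sp[sp$channel == "Fz", ]
  expect_lt(fz$peak_amplitude[fz$bin_center_hz == 1.0],
            left$peak_amplitude[left$bin_center_hz == 1.0])
})

test_that("coherence respects time-reversal symmetry on synthetic data", {
  # correlating reversed flow with reversed EEG reproduces the direct
  # amplitude (lags mirrored onto the negative axis, so compare amplitude
  # over a symmetric window)
  fs <- 250
  x <- zero_phase(narrowband_design(2, 0.4, fs),
                  withr::with_seed(3, stats::rnorm(2000)))
  y <- c(rep(0, 50), x)[1:2000] +
    withr::with_seed(4, stats::rnorm(2000, sd = 0.3))
  fwd <- lagged_correlation(x, y, fs, c(-400, 400))
  rev_ <- lagged_correlation(rev(x), rev(y), fs, c(-400, 400))
  expect_equal(rev_$peak_amplitude, fwd$peak_amplitude, tolerance = 0.05)
  expect_equal(rev_$peak_time_ms, -fwd$peak_time_ms, tolerance = 1e-9)
})

test_that("low-frequency bins are flagged low-confidence but retained", {
  cohort <- small_cohort()
  rec <- preprocess_continuous(cohort$recordings[[1]])
  sp <- instance_spectrum(rec, cohort$flows$direct,
                          grid = frequency_grid(0.2, 0.6, 0.2),
                          aggregate = "profile_mean")
  expect_true(all(sp$low_confidence[sp$bin_center_hz == 0.2]))
  expect_false(any(sp$low_confidence[sp$bin_center_hz == 0.6]))
  expect_equal(nrow(sp), 3 * 26)     # retained for all 26 scalp channels
})
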
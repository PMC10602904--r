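# Synthetic cohort generator.
#
# The study design being emulated: two populations (a "comprehending" group of
# 24 and a control group of 20) watch short videos of a moving articulator in
# two conditions -- direct, and time-reversed (same low-level statistics,
# incomprehensible). EEG is 1/f background noise plus band-limited, lagged,
# region-weighted copies of each video's optical-flow magnitude timeseries;
# which region x frequency cells carry entrainment, and at what lag, differs
# between populations, and reversal attenuates the entrained component.

#' Default embedded entrainment structure
#'
#' One row per (group, region, frequency, lag, snr) cell. Group `a` carries
#' low-frequency entrainment over anterior/posterior/left regions around 1 Hz
#' plus a weaker anterior alpha-band (9.4 Hz) component; group `b` lacks the
#' alpha component and has a weaker left-hemisphere cell. `snr` is the RMS of
#' the injected narrowband component relative to the in-band RMS of the
#' channel's background noise.
#'
#' @return data.frame with columns `group`, `region`, `frequency_hz`,
#'   `lag_ms`, `snr`.
#' @export
default_entrainment_cells <- function() {
  data.frame(
    group = c("a", "a", "a", "a", "a", "b", "b", "b", "b"),
    region = c("anterior", "posterior", "left", "right", "anterior",
               "anterior", "posterior", "right", "left"),
    frequency_hz = c(1.0, 1.0, 1.0, 1.2, 9.4, 1.0, 1.0, 1.2, 1.0),
    lag_ms = c(200, 150, 200, 150, 120, 180, 150, 140, 250),
    snr = c(6, 6, 6, 6, 4, 6, 6, 6, 3),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the synthetic generator: cohort sizes, video
#' timing, EEG rate and montage, the embedded entrainment cells, background
#' noise spectrum, and the master seed. Identical specs (same seed) produce
#' bit-identical cohorts.
#'
#' @param n_group_a,n_group_b participants per group (defaults 24 and 20).
#' @param n_videos_per_condition stimulus videos per condition (default 2).
#' @param video_duration_s length-2 range of video durations in seconds,
#'   inside `[5, 7]`; individual videos are spaced evenly across the range.
#' @param frame_rate_hz video frame rate (default 30).
#' @param eeg_rate_hz EEG sampling rate (default 500).
#' @param channel_labels scalp montage labels (default [montage_scalp()]).
#' @param entrainment_cells data.frame as in [default_entrainment_cells()].
#' @param noise_exponent 1/f spectral slope of the background noise
#'   (default 1).
#' @param noise_rms_uv RMS of the background noise in microvolts (default 8).
#' @param reversal_snr_factor named numeric: multiplicative attenuation of
#'   every cell's snr in the reversed condition, per group
#'   (default `c(a = 0.3, b = 0.5)`).
#' @param eog list controlling ocular channels: `enable`, and scalar
#'   propagation factors `veog_prop`, `heog_prop` of the bipolar EOG signals
#'   into every scalp channel.
#' @param seed integer master seed.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_group_a = 24L, n_group_b = 20L,
                       n_videos_per_condition = 2L,
                       video_duration_s = c(5, 7),
                       frame_rate_hz = 30,
                       eeg_rate_hz = 500,
                       channel_labels = montage_scalp(),
                       entrainment_cells = default_entrainment_cells(),
                       noise_exponent = 1,
                       noise_rms_uv = 8,
                       reversal_snr_factor = c(a = 0.3, b = 0.5),
                       eog = list(enable = TRUE, veog_prop = 0.08,
                                  heog_prop = 0.04),
                       seed = 1L) {
  counts <- c(n_group_a, n_group_b, n_videos_per_condition,
              frame_rate_hz, eeg_rate_hz)
  if (any(counts <= 0)) stopf("all counts and rates must be positive")
  if (length(video_duration_s) == 1) {
    video_duration_s <- rep(video_duration_s, 2)
  }
  if (video_duration_s[1] < 5 - 1e-9 || video_duration_s[2] > 7 + 1e-9 ||
      video_duration_s[1] > video_duration_s[2]) {
    stopf("video_duration_s must be a range inside [5, 7]")
  }
  ec <- entrainment_cells
  if (nrow(ec)) {
    if (any(ec$frequency_hz < 0.2 | ec$frequency_hz > 12.4)) {
      stopf("entrainment frequencies must lie in [0.2, 12.4] Hz")
    }
    if (!all(ec$region %in% REGIONS)) {
      stopf("entrainment regions must be in {%s}",
            paste(REGIONS, collapse = ", "))
    }
    if (any(ec$snr < 0)) stopf("snr must be >= 0")
  }
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_videos_per_condition = as.integer(n_videos_per_condition),
    video_duration_s = video_duration_s, frame_rate_hz = frame_rate_hz,
    eeg_rate_hz = eeg_rate_hz, channel_labels = channel_labels,
    entrainment_cells = ec, noise_exponent = noise_exponent,
    noise_rms_uv = noise_rms_uv, reversal_snr_factor = reversal_snr_factor,
    eog = eog, seed = as.integer(seed)), class = "synth_spec")
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain by
#' `f^(-exponent/2)` (flat below 0.1 Hz to keep finite power) and returned
#' normalised to unit RMS.
#'
#' @param n samples.
#' @param rate_hz sampling rate.
#' @param exponent spectral slope of the power spectrum (1 = pink).
#' @return numeric vector of length `n`, unit RMS.
#' @export
one_over_f_noise <- function(n, rate_hz, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, rate_hz, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rate_hz - f)           # two-sided frequency axis
  f <- pmax(f, 0.1)                   # flatten below 0.1 Hz
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize an optical-flow magnitude timeseries
#'
#' A band-limited (< 12 Hz), positively-valued series at the video frame
#' rate, emulating the global motion-energy signal of a video with a moving
#' articulator: 1/f-weighted Gaussian noise, band-limited, then shifted to
#' be non-negative.
#'
#' @param duration_s video duration in seconds.
#' @param frame_rate_hz frame rate.
#' @param seed integer seed.
#' @param source_id stimulus identifier.
#' @return a [flow_timeseries()].
#' @export
synth_flow <- function(duration_s, frame_rate_hz = 30, seed = 1L,
                       source_id = "synth") {
  n <- round(duration_s * frame_rate_hz) - 1
  if (n < 2) stopf("duration too short for a flow series")
  x <- with_seed(seed, {
    v <- one_over_f_noise(n, frame_rate_hz, exponent = 0.8)
    X <- stats::fft(v)
    f <- seq(0, frame_rate_hz, length.out = n + 1)[seq_len(n)]
    f <- pmin(f, frame_rate_hz - f)
    X[f > 12] <- 0                   # hard band limit at 12 Hz
    Re(stats::fft(X, inverse = TRUE)) / n
  })
  x <- x / stats::sd(x)
  flow_timeseries(x - min(x), frame_rate_hz, source_id)
}

#' Render a synthetic video of a moving ellipse
#'
#' A bright soft-edged ellipse on a dark background whose centroid follows a
#' configurable trajectory. The per-frame centroid displacement magnitude is
#' returned alongside as ground-truth motion.
#'
#' @param duration_s duration in seconds.
#' @param frame_rate_hz frame rate.
#' @param width,height frame size in pixels.
#' @param trajectory `"bandlimited"` (default; band-limited random walk),
#'   `"stationary"`, `"constant"` (constant horizontal velocity), or
#'   `"sinusoid"` (horizontal oscillation).
#' @param speed_px pixels/frame for `"constant"`.
#' @param osc_freq_hz,osc_amp_px frequency and amplitude for `"sinusoid"`.
#' @param axes_px ellipse semi-axes in pixels.
#' @param seed integer seed (used by `"bandlimited"`).
#' @return list with `frames` (height x width x n array in `[0, 1]`),
#'   `truth` (length n-1 centroid displacement magnitudes, px/frame),
#'   `frame_rate_hz`.
#' @export
make_video <- function(duration_s = 5, frame_rate_hz = 30,
                       width = 64, height = 64,
                       trajectory = c("bandlimited", "stationary",
                                      "constant", "sinusoid"),
                       speed_px = 1, osc_freq_hz = 1, osc_amp_px = 8,
                       axes_px = c(6, 9), seed = 1L) {
  trajectory <- match.arg(trajectory)
  n <- round(duration_s * frame_rate_hz)
  if (n < 1) stopf("zero frames requested")
  t <- seq_len(n) - 1
  cx0 <- width / 2; cy0 <- height / 2
  path <- switch(trajectory,
    stationary = cbind(rep(cx0, n), rep(cy0, n)),
    constant = cbind(cx0 - speed_px * (n - 1) / 2 + speed_px * t,
                     rep(cy0, n)),
    sinusoid = cbind(cx0 + osc_amp_px *
                       sin(2 * pi * osc_freq_hz * t / frame_rate_hz),
                     rep(cy0, n)),
    bandlimited = with_seed(seed, {
      lim <- function() {
        x <- one_over_f_noise(n, frame_rate_hz, exponent = 1.5)
        x / max(abs(x)) * min(width, height) / 5
      }
      cbind(cx0 + lim(), cy0 + lim())
    })
  )
  xs <- seq_len(width); ys <- seq_len(height)
  frames <- array(0, dim = c(height, width, n))
  for (i in seq_len(n)) {
    dx2 <- outer(rep(1, height), ((xs - path[i, 1]) / axes_px[1])^2)
    dy2 <- outer(((ys - path[i, 2]) / axes_px[2])^2, rep(1, width))
    r2 <- dx2 + dy2
    frames[, , i] <- exp(-pmax(r2 - 1, 0) * 2)  # flat core, soft edge
  }
  truth <- if (n > 1) {
    sqrt(rowSums((path[-1, , drop = FALSE] -
                    path[-n, , drop = FALSE])^2))
  } else numeric(0)
  list(frames = frames, truth = truth, frame_rate_hz = frame_rate_hz)
}

# in-band RMS of a signal at a narrowband cell
inband_rms <- function(x, center_hz, rate_hz, bandwidth_hz = 0.2) {
  nb <- narrowband_design(center_hz, bandwidth_hz, rate_hz)
  sqrt(mean(zero_phase(nb, x)^2))
}

#' Synthesize one EEG recording entrained to optical flow
#'
#' Each scalp channel is 1/f background noise plus, for every entrainment
#' cell applicable to this participant's group and the channel's region, an
#' snr-scaled, lag-delayed, narrowband-filtered copy of the stimulus flow
#' resampled to the EEG rate. In the reversed condition the injected snr is
#' attenuated by the group's `reversal_snr_factor`. Mastoid and bipolar EOG
#' channel pairs (with known scalp propagation) are appended, and a stimulus
#' event is marked at each video onset.
#'
#' @param spec a [synth_spec()].
#' @param flow a [flow_timeseries()] or list of them (one per video shown).
#' @param participant_id participant identifier.
#' @param group `"a"` or `"b"`.
#' @param condition `"direct"` or `"reversed"`. The caller supplies the flow
#'   already time-reversed for the reversed condition; this argument controls
#'   only the snr attenuation and metadata.
#' @param eog_mixing optional override of the EOG propagation factors,
#'   `list(veog = , heog = )`, scalars or named per-channel vectors.
#' @return an [eeg_recording()].
#' @export
make_eeg <- function(spec, flow, participant_id, group = "a",
                     condition = c("direct", "reversed"),
                     eog_mixing = NULL) {
  condition <- match.arg(condition)
  if (inherits(flow, "flow_timeseries")) flow <- list(flow)
  fs <- spec$eeg_rate_hz
  labels <- spec$channel_labels
  regions <- vapply(labels, channel_region, character(1))
  cells <- spec$entrainment_cells
  cells <- cells[cells$group == group, , drop = FALSE]
  for (r in unique(cells$region)) {
    if (!any(regions == r, na.rm = TRUE)) {
      stopf("entrainment cell targets region '%s' but no montage channel maps to it", r)
    }
  }
  snr_fac <- if (condition == "reversed") {
    spec$reversal_snr_factor[[group]]
  } else 1
  pre_s <- 1; post_s <- 1.2   # post covers the full lag search window
  durs <- vapply(flow, function(f) (length(f$values) + 1) / f$frame_rate_hz,
                 numeric(1))
  starts <- integer(length(flow))
  total <- 0L
  for (i in seq_along(flow)) {
    starts[i] <- total + round(pre_s * fs) + 1L
    total <- total + as.integer(round((pre_s + durs[i] + post_s) * fs))
  }
  seed <- derive_seed(spec$seed, paste("eeg", participant_id, condition))
  aux <- montage_aux()
  n_scalp <- length(labels)
  all_labels <- c(labels, aux$mastoids, aux$heog, aux$veog)
  with_seed(seed, {
    data <- matrix(0, nrow = length(all_labels), ncol = total)
    for (ch in seq_len(n_scalp)) {
      data[ch, ] <- one_over_f_noise(total, fs, spec$noise_exponent) *
        spec$noise_rms_uv
    }
    # per-channel injection amplitude: snr x in-band RMS of that channel's
    # background noise, computed once per (cell, channel)
    amps <- matrix(0, nrow = nrow(cells), ncol = n_scalp)
    for (ci in seq_len(nrow(cells))) {
      for (ch in which(regions == cells$region[ci])) {
        amps[ci, ch] <- cells$snr[ci] * snr_fac *
          inband_rms(data[ch, ], cells$frequency_hz[ci], fs)
      }
    }
    # entrained components, per video x applicable cell
    for (i in seq_along(flow)) {
      fres <- resample_flow(flow[[i]], fs)
      v <- fres$values - mean(fres$values)
      for (ci in seq_len(nrow(cells))) {
        cell <- cells[ci, ]
        nb <- narrowband_design(cell$frequency_hz, 0.2, fs)
        comp <- zero_phase(nb, v)
        comp <- comp / sqrt(mean(comp^2))
        lag_smp <- round(cell$lag_ms / 1000 * fs)
        comp <- c(rep(0, lag_smp), comp)[seq_along(comp)]
        idx <- starts[i]:min(starts[i] + length(comp) - 1L, total)
        for (ch in which(regions == cell$region)) {
          data[ch, idx] <- data[ch, idx] + amps[ci, ch] * comp[seq_along(idx)]
        }
      }
    }
    # mastoids: background noise only, lower amplitude
    for (j in 1:2) {
      data[n_scalp + j, ] <- one_over_f_noise(total, fs,
                                              spec$noise_exponent) * 5
    }
    # ocular channels and their propagation into scalp channels
    if (isTRUE(spec$eog$enable)) {
      blink <- eog_blink_train(total, fs)
      sacc <- eog_saccade_train(total, fs)
      data[n_scalp + 3, ] <- sacc + stats::rnorm(total, sd = 3)    # HEOGL
      data[n_scalp + 4, ] <- -sacc + stats::rnorm(total, sd = 3)   # HEOGR
      data[n_scalp + 5, ] <- blink + stats::rnorm(total, sd = 3)   # VEOGU
      data[n_scalp + 6, ] <- -0.3 * blink + stats::rnorm(total, sd = 3)
      veog_b <- data[n_scalp + 5, ] - data[n_scalp + 6, ]
      heog_b <- data[n_scalp + 3, ] - data[n_scalp + 4, ]
      vp <- eog_mixing$veog %||% spec$eog$veog_prop
      hp <- eog_mixing$heog %||% spec$eog$heog_prop
      for (ch in seq_len(n_scalp)) {
        vpi <- if (length(vp) > 1) vp[[labels[ch]]] else vp
        hpi <- if (length(hp) > 1) hp[[labels[ch]]] else hp
        data[ch, ] <- data[ch, ] + vpi * veog_b + hpi * heog_b
      }
    }
    events <- data.frame(
      sample = starts, code = seq_along(flow),
      video_id = vapply(flow, function(f) as.character(f$source_id),
                        character(1)))
    eeg_recording(
      data, fs, all_labels,
      channel_types = c(rep("eeg", n_scalp), rep("mastoid", 2),
                        rep("eog", 4)),
      events = events,
      meta = list(participant = participant_id, group = group,
                  condition = condition))
  })
}

# sum of smooth blink-shaped bumps at random times, ~150 uV
eog_blink_train <- function(n, fs, rate_per_s = 0.25, amp = 150) {
  x <- numeric(n)
  n_blinks <- stats::rpois(1, rate_per_s * n / fs)
  if (n_blinks == 0) return(x)
  centers <- sort(stats::runif(n_blinks, 1, n))
  width <- 0.15 * fs
  t <- seq_len(n)
  for (c0 in centers) x <- x + amp * exp(-((t - c0) / width)^2)
  x
}

# low-passed random telegraph signal emulating horizontal saccades, ~40 uV
eog_saccade_train <- function(n, fs, switch_per_s = 0.5, amp = 40) {
  n_seg <- max(1, stats::rpois(1, switch_per_s * n / fs))
  bounds <- unique(c(1, sort(sample.int(n, n_seg)), n + 1))
  x <- numeric(n)
  lev <- amp * (stats::rbinom(length(bounds) - 1, 1, 0.5) * 2 - 1)
  for (i in seq_len(length(bounds) - 1)) {
    x[bounds[i]:(bounds[i + 1] - 1)] <- lev[i]
  }
  lp <- butter_sos(2, 5, fs, "low")
  zero_phase(lp, x)
}

#' Generate the full synthetic cohort
#'
#' Draws the stimulus video set (as flow timeseries), then one EEG recording
#' per participant x condition; the reversed condition uses the time-reversed
#' flow of each video. With default group sizes this yields
#' `(24 + 20) x 2 = 88` instances.
#'
#' @param spec a [synth_spec()].
#' @return list with `recordings` (list of [eeg_recording()], one per
#'   instance), `flows` (list with `direct` and `reversed` lists of
#'   [flow_timeseries()] keyed by video id), and `meta` (data.frame with one
#'   row per instance: `participant`, `group`, `condition`).
#' @export
make_cohort <- function(spec) {
  nv <- spec$n_videos_per_condition
  durs <- if (nv == 1) mean(spec$video_duration_s) else {
    seq(spec$video_duration_s[1], spec$video_duration_s[2], length.out = nv)
  }
  direct <- lapply(seq_len(nv), function(i) {
    synth_flow(durs[i], spec$frame_rate_hz,
               seed = derive_seed(spec$seed, paste("flow", i)),
               source_id = sprintf("vid%02d", i))
  })
  names(direct) <- vapply(direct, function(f) f$source_id, character(1))
  reversed <- lapply(direct, function(f) {
    flow_timeseries(rev(f$values), f$frame_rate_hz, f$source_id)
  })
  groups <- c(rep("a", spec$n_group_a), rep("b", spec$n_group_b))
  pids <- sprintf("p%02d", seq_along(groups))
  meta <- expand.grid(condition = c("direct", "reversed"),
                      participant = pids, stringsAsFactors = FALSE)
  meta$group <- groups[match(meta$participant, pids)]
  meta <- meta[order(meta$group, meta$participant, meta$condition),
               c("participant", "group", "condition")]
  rownames(meta) <- NULL
  recordings <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    flows <- if (meta$condition[i] == "direct") direct else reversed
    recordings[[i]] <- make_eeg(spec, flows, meta$participant[i],
                                meta$group[i], meta$condition[i])
  }
  names(recordings) <- paste(meta$participant, meta$condition, sep = "_")
  list(recordings = recordings,
       flows = list(direct = direct, reversed = reversed),
       meta = meta)
}
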
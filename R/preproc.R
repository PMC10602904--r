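# EEG preprocessing chain: mastoid re-reference -> zero-phase Butterworth
# band-pass -> regression-based ocular correction -> epoching from stimulus
# onsets -> amplitude-based artifact rejection. Filtering precedes epoching
# so epochs inherit no per-segment filter edge artifacts.

#' Re-reference scalp channels to the mastoid average
#'
#' Subtracts the mean of the left and right mastoid channels from every
#' scalp channel. Mastoids are retained and marked as reference channels;
#' EOG channels are untouched.
#'
#' @param rec an [eeg_recording()].
#' @param mastoids labels of the two mastoid channels.
#' @return re-referenced [eeg_recording()].
#' @export
rereference_mastoids <- function(rec, mastoids = c("M1", "M2")) {
  idx <- match(mastoids, rec$channel_labels)
  if (anyNA(idx)) {
    stopf("mastoid channel '%s' not found",
          mastoids[which(is.na(idx))[1]])
  }
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  out <- rec
  scalp <- scalp_channels(rec)
  out$data[scalp, ] <- sweep(rec$data[scalp, , drop = FALSE], 2, ref)
  out$channel_types[idx] <- "ref"
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' The stated roll-off is converted to filter order at 6 dB/oct per pole
#' (48 dB/oct = 8th order), designed as cascaded second-order sections for
#' numerical stability at a 0.1 Hz edge, and applied forward-backward (zero
#' phase). High-pass and low-pass are applied as separate cascades. Only
#' scalp and mastoid channels are filtered; EOG channels are band-passed
#' identically so regression-based ocular correction stays consistent.
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz high-pass cutoff (default 0.1 Hz).
#' @param lp_hz low-pass cutoff (default 30 Hz).
#' @param rolloff_db_oct roll-off steepness (default 48 dB/oct).
#' @return filtered [eeg_recording()].
#' @export
bandpass <- function(rec, hp_hz = 0.1, lp_hz = 30, rolloff_db_oct = 48) {
  if (!(hp_hz < lp_hz && lp_hz < rec$rate_hz / 2)) {
    stopf("need hp < lp < Nyquist; got %g, %g at rate %g",
          hp_hz, lp_hz, rec$rate_hz)
  }
  order <- max(2, 2 * round(rolloff_db_oct / 12))
  hp <- butter_sos(order, hp_hz, rec$rate_hz, "high")
  lp <- butter_sos(order, lp_hz, rec$rate_hz, "low")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- zero_phase(lp, zero_phase(hp, rec$data[ch, ]))
  }
  out
}

#' Regression-based ocular artifact correction
#'
#' The raw-regression variant of the classic propagation-factor method:
#' bipolar HEOG and VEOG signals are formed from their electrode pairs, and
#' per scalp channel the least-squares propagation factors `b_H`, `b_V` are
#' estimated over the whole recording and the fitted ocular contribution
#' subtracted. (The original ERP-subtraction variant averages event-locked
#' activity out first; the raw form is used because single-trial coherence,
#' not ERPs, is the downstream target.)
#'
#' @param rec an [eeg_recording()] containing the four EOG electrodes.
#' @param heog,veog label pairs forming the bipolar HEOG and VEOG signals.
#' @return corrected [eeg_recording()], with the estimated factors in
#'   `$meta$ocular_factors` (data.frame: channel, b_h, b_v).
#' @export
correct_ocular <- function(rec, heog = c("HEOGL", "HEOGR"),
                           veog = c("VEOGU", "VEOGL")) {
  hi <- match(heog, rec$channel_labels)
  vi <- match(veog, rec$channel_labels)
  if (anyNA(c(hi, vi))) stopf("EOG channel pair(s) missing from recording")
  h <- rec$data[hi[1], ] - rec$data[hi[2], ]
  v <- rec$data[vi[1], ] - rec$data[vi[2], ]
  out <- rec
  scalp <- scalp_channels(rec)
  if (stats::var(h) < 1e-12 && stats::var(v) < 1e-12) {
    warnf("EOG variance ~ 0; propagation factors set to 0")
    out$meta$ocular_factors <- data.frame(
      channel = rec$channel_labels[scalp], b_h = 0, b_v = 0)
    return(out)
  }
  X <- cbind(h - mean(h), v - mean(v))
  XtX <- crossprod(X)
  factors <- matrix(0, nrow = length(scalp), ncol = 2)
  for (k in seq_along(scalp)) {
    y <- rec$data[scalp[k], ]
    b <- solve(XtX, crossprod(X, y - mean(y)))
    out$data[scalp[k], ] <- y - X %*% b
    factors[k, ] <- b
  }
  out$meta$ocular_factors <- data.frame(
    channel = rec$channel_labels[scalp], b_h = factors[, 1],
    b_v = factors[, 2])
  out
}

#' Epoch a recording from stimulus onsets
#'
#' Extracts `[window_s[1], window_s[2])` second epochs relative to each event
#' onset: `(window_s[2] - window_s[1]) * rate` samples per trial. An event
#' whose window overruns the recording yields a trial flagged rejected (with
#' zero-filled data), never a silently dropped one.
#'
#' @param rec an [eeg_recording()] with events.
#' @param window_s epoch window in seconds relative to onset (default
#'   `c(0, 5)`).
#' @return an [epoch_set()].
#' @export
epoch <- function(rec, window_s = c(0, 5)) {
  ns <- as.integer(round((window_s[2] - window_s[1]) * rec$rate_hz))
  ev <- rec$events
  n_trial <- nrow(ev)
  epochs <- array(0, dim = c(n_trial, nrow(rec$data), ns))
  mask <- rep(FALSE, n_trial)
  reason <- rep(NA_character_, n_trial)
  off <- as.integer(round(window_s[1] * rec$rate_hz))
  for (i in seq_len(n_trial)) {
    a <- ev$sample[i] + off
    b <- a + ns - 1L
    if (a < 1 || b > ncol(rec$data)) {
      mask[i] <- TRUE
      reason[i] <- "window outside recording"
      next
    }
    epochs[i, , ] <- rec$data[, a:b]
  }
  meta <- data.frame(trial = seq_len(n_trial),
                     code = ev$code,
                     video_id = if ("video_id" %in% names(ev)) {
                       ev$video_id
                     } else rep(NA_character_, n_trial),
                     participant = rep(rec$meta$participant %||%
                                         NA_character_, n_trial),
                     group = rep(rec$meta$group %||% NA_character_,
                                 n_trial),
                     condition = rep(rec$meta$condition %||% NA_character_,
                                     n_trial),
                     rejection_reason = reason,
                     stringsAsFactors = FALSE)
  epoch_set(epochs, rec$rate_hz, rec$channel_labels, rec$channel_types,
            meta, mask, window_s)
}

#' Amplitude-based artifact rejection
#'
#' Flags every trial in which any scalp-channel sample exceeds
#' `+/- limit_uv` microvolts. Flags accumulate (already-rejected trials stay
#' rejected); trials are never dropped.
#'
#' @param epochs an [epoch_set()].
#' @param limit_uv rejection bound in microvolts (default 75).
#' @return the [epoch_set()] with an updated rejection mask.
#' @export
reject_amplitude <- function(epochs, limit_uv = 75) {
  if (limit_uv <= 0) stopf("limit_uv must be positive")
  scalp <- which(epochs$channel_types == "eeg")
  for (i in seq_len(dim(epochs$epochs)[1])) {
    x <- epochs$epochs[i, scalp, ]
    if (any(abs(x) > limit_uv)) {
      if (!epochs$rejection_mask[i]) {
        epochs$trial_meta$rejection_reason[i] <-
          sprintf("amplitude beyond +/-%g uV", limit_uv)
      }
      epochs$rejection_mask[i] <- TRUE
    }
  }
  epochs
}

#' Full preprocessing chain
#'
#' `rereference -> bandpass -> ocular correction -> epoch -> amplitude
#' rejection`, each step as documented in its own function. Deterministic:
#' re-running on identical input is bit-identical.
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz,lp_hz,rolloff_db_oct band-pass parameters.
#' @param window_s epoch window, seconds.
#' @param limit_uv rejection bound, microvolts.
#' @param ocular apply ocular correction (default `TRUE` when EOG channels
#'   are present).
#' @return an [epoch_set()].
#' @export
preprocess <- function(rec, hp_hz = 0.1, lp_hz = 30, rolloff_db_oct = 48,
                       window_s = c(0, 5), limit_uv = 75,
                       ocular = NULL) {
  rec <- preprocess_continuous(rec, hp_hz, lp_hz, rolloff_db_oct, ocular)
  reject_amplitude(epoch(rec, window_s), limit_uv)
}

#' Continuous part of the preprocessing chain
#'
#' `rereference -> bandpass -> ocular correction`, returning the continuous
#' recording (not yet epoched) so downstream narrowband analysis can filter
#' with full temporal context before windowing.
#'
#' @inheritParams preprocess
#' @return a preprocessed [eeg_recording()].
#' @export
preprocess_continuous <- function(rec, hp_hz = 0.1, lp_hz = 30,
                                  rolloff_db_oct = 48, ocular = NULL) {
  rec <- rereference_mastoids(rec)
  rec <- bandpass(rec, hp_hz, lp_hz, rolloff_db_oct)
  if (is.null(ocular)) ocular <- any(rec$channel_types == "eog")
  if (ocular) rec <- correct_ocular(rec)
  rec
}
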
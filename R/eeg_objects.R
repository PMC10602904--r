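#' Construct a multichannel EEG recording
#'
#' Container for continuous multichannel EEG: a channels-by-samples matrix in
#' microvolts, sampling rate, channel labels/types, and stimulus event
#' markers.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param rate_hz sampling rate in samples/s.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param channel_types character vector, one of `"eeg"`, `"mastoid"`,
#'   `"eog"` per channel (default: all `"eeg"`).
#' @param events data.frame with columns `sample` (1-based onset sample),
#'   `code` (stimulus code), and optionally `video_id`.
#' @param meta named list of free-form metadata (participant, group,
#'   condition, ...).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, channel_labels,
                          channel_types = NULL, events = NULL, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) {
    stopf("%d channel labels for %d data rows",
          length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) {
    stopf("channel labels must be unique")
  }
  if (is.null(channel_types)) channel_types <- rep("eeg", nrow(data))
  if (is.null(events)) {
    events <- data.frame(sample = integer(), code = integer(),
                         video_id = character())
  }
  if (nrow(events) && any(events$sample < 1 | events$sample > ncol(data))) {
    stopf("event sample index outside the recording")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate_hz = rate_hz,
                 channel_labels = channel_labels,
                 channel_types = channel_types,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$events)))
  invisible(x)
}

scalp_channels <- function(rec) which(rec$channel_types == "eeg")

#' Construct an epoched EEG dataset
#'
#' @param epochs numeric array, trials x channels x samples.
#' @param rate_hz sampling rate in Hz.
#' @param channel_labels channel labels (second dimension).
#' @param channel_types channel types as in [eeg_recording()].
#' @param trial_meta data.frame with one row per trial.
#' @param rejection_mask logical per trial; `TRUE` = rejected. Rejected trials
#'   are flagged, never dropped.
#' @param window_s epoch window relative to onset, seconds.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, rate_hz, channel_labels, channel_types = NULL,
                      trial_meta = NULL, rejection_mask = NULL,
                      window_s = c(0, 5)) {
  stopifnot(length(dim(epochs)) == 3)
  n_trial <- dim(epochs)[1]
  if (is.null(rejection_mask)) rejection_mask <- rep(FALSE, n_trial)
  if (is.null(trial_meta)) trial_meta <- data.frame(trial = seq_len(n_trial))
  if (is.null(channel_types)) channel_types <- rep("eeg", dim(epochs)[2])
  structure(list(epochs = epochs, rate_hz = rate_hz,
                 channel_labels = channel_labels,
                 channel_types = channel_types,
                 trial_meta = trial_meta,
                 rejection_mask = rejection_mask,
                 window_s = window_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%d rejected)\n",
    dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$rate_hz,
    sum(x$rejection_mask)))
  invisible(x)
}

#' Construct an optical-flow magnitude timeseries
#'
#' One value per frame transition: the global (summed over pixels) optical
#' flow velocity magnitude, so a video of `n` frames yields `n - 1` values.
#'
#' @param values non-negative numeric vector.
#' @param frame_rate_hz frame rate of the source video, frames/s.
#' @param source_id stimulus identifier.
#' @return object of class `flow_timeseries`.
#' @export
flow_timeseries <- function(values, frame_rate_hz, source_id = NA_character_) {
  if (length(values) == 0) stopf("empty flow timeseries")
  if (any(values < 0)) stopf("flow magnitudes must be non-negative")
  structure(list(values = as.numeric(values), frame_rate_hz = frame_rate_hz,
                 source_id = source_id),
            class = "flow_timeseries")
}

#' @export
print.flow_timeseries <- function(x, ...) {
  cat(sprintf("<flow_timeseries> %d transitions @ %g fps (source %s)\n",
              length(x$values), x$frame_rate_hz, x$source_id))
  invisible(x)
}
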
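# Frequency-resolved stimulus-brain coherence.
#
# Both the stimulus flow series and each EEG channel are narrowband-filtered
# (second-order IIR, zero-phase) at every bin of a 0.2-12.4 Hz grid; the
# coherence at a bin is the maximal-magnitude lagged Pearson correlation over
# a positive-lag window (brain follows stimulus), and the lag of that peak is
# the coherence timepoint. This maximal lagged correlation is the rank-1
# special case of CCA on a univariate narrowband pair; a delay-embedded CCA
# mode is provided as a sensitivity cross-check.

#' Analysis frequency grid
#'
#' Bin centres from `from` to `to` in steps of `by`; defaults give the 62-bin
#' 0.2-12.4 Hz grid used throughout.
#'
#' @param from,to,by grid limits and step, Hz.
#' @param bandwidth_hz per-bin -3 dB passband width (default 0.2).
#' @return object of class `frequency_grid` with `centers` and
#'   `bandwidth_hz`.
#' @export
frequency_grid <- function(from = 0.2, to = 12.4, by = 0.2,
                           bandwidth_hz = 0.2) {
  centers <- round(seq(from, to, by = by), 10)
  if (any(diff(centers) <= 0)) stopf("grid centers must be increasing")
  structure(list(centers = centers, bandwidth_hz = bandwidth_hz),
            class = "frequency_grid")
}

#' Resample a flow timeseries to a target rate
#'
#' Band-limited interpolation in the frequency domain: the line through the
#' series endpoints is removed (suppressing periodicity artifacts), the
#' spectrum is zero-padded or truncated to the target length
#' `round(n * target / source)` (so the effective rate matches the target to
#' within one part in `n`), and the trend restored. Residual error is
#' concentrated in the few samples at either end.
#'
#' @param flow a [flow_timeseries()].
#' @param target_hz target sampling rate; must be at least twice the top
#'   analysis frequency (12.4 Hz).
#' @return a [flow_timeseries()] at `target_hz`.
#' @export
resample_flow <- function(flow, target_hz) {
  x <- flow$values
  if (length(x) == 0) stopf("empty flow series")
  if (target_hz < 2 * 12.4) {
    stopf("target rate %g Hz below 2 x 12.4 Hz", target_hz)
  }
  if (abs(target_hz - flow$frame_rate_hz) < 1e-9) return(flow)
  n <- length(x)
  m <- as.integer(round(n * target_hz / flow$frame_rate_hz))
  slope <- (x[n] - x[1]) / (n - 1)
  base <- x[1] + slope * (seq_len(n) - 1)
  X <- stats::fft(x - base)
  Y <- complex(real = rep(0, m))
  kmax <- min(floor((n - 1) / 2), floor((m - 1) / 2))
  Y[1] <- X[1]
  if (kmax >= 1) {
    Y[2:(kmax + 1)] <- X[2:(kmax + 1)]
    Y[m - (1:kmax) + 1] <- X[n - (1:kmax) + 1]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n +
    x[1] + slope * (seq_len(m) - 1) * (n / m)
  flow_timeseries(pmax(y, 0), target_hz, flow$source_id)
}

#' Narrowband-filter a series at one grid bin
#'
#' Second-order IIR band-pass applied forward-backward (zero phase, so peak
#' lags remain interpretable).
#'
#' @param x numeric series.
#' @param center_hz bin centre, Hz.
#' @param bandwidth_hz -3 dB bandwidth, Hz.
#' @param rate_hz sampling rate, Hz.
#' @return filtered series.
#' @export
narrowband <- function(x, center_hz, bandwidth_hz = 0.2, rate_hz) {
  zero_phase(narrowband_design(center_hz, bandwidth_hz, rate_hz), x)
}

# raw lagged cross-products via FFT: S_xy(tau) = sum_i x_i y_{i+tau},
# tau = 0..max_lag; x and y may have different lengths
cross_sums <- function(x, y, max_lag) {
  nx <- length(x); ny <- length(y)
  nfft <- stats::nextn(max(nx, ny) + max_lag + 1, 2)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  Y <- stats::fft(c(y, rep(0, nfft - ny)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  cc[seq_len(max_lag + 1)]
}

#' Maximal lagged Pearson correlation between two equal-rate series
#'
#' For each non-negative lag `tau` on the sample grid inside `lag_window_ms`,
#' computes the Pearson correlation of `x(t)` with `y(t + tau)` over the
#' valid overlap, and returns the peak of `|r|`, its lag in ms, and the sign
#' of `r` at the peak. If `y` extends beyond the length of `x` (continuous
#' context after the analysis window, e.g. post-stimulus recording), that
#' context is used so the overlap stays at full window length for as many
#' lags as the context covers; otherwise the overlap shrinks with the lag.
#' All per-lag sums come from cumulative sums plus one FFT
#' cross-correlation, so cost is `O(n log n)` regardless of window length.
#'
#' @param x stimulus-side series (narrowband flow over the analysis window).
#' @param y response-side series (narrowband EEG from window start, possibly
#'   longer than `x`).
#' @param rate_hz common sampling rate.
#' @param lag_window_ms length-2 window of lags to search, ms (default
#'   `c(0, 1000)`; positive lags only, brain follows stimulus).
#' @param center_hz optional bin centre used for the low-confidence flag
#'   (overlap shorter than 2 cycles).
#' @param return_profile also return the full `r(tau)` profile and the lag
#'   grid (used for trial-averaged profile localisation).
#' @return list `peak_amplitude` (max `|r|`), `peak_time_ms`, `sign`,
#'   `low_confidence`, and with `return_profile` also `r` and `lag_ms`.
#'   Zero-variance input yields amplitude 0 and `peak_time_ms = NA` (flagged
#'   missing, not fabricated).
#' @export
lagged_correlation <- function(x, y, rate_hz, lag_window_ms = c(0, 1000),
                               center_hz = NULL, return_profile = FALSE) {
  if (lag_window_ms[1] < 0) {
    # negative lags: r(-tau) of (x, y) is r(tau) of (y, x); evaluate the two
    # half-windows and keep the larger peak
    n <- min(length(x), length(y))
    neg <- lagged_correlation(y[seq_len(n)], x[seq_len(n)], rate_hz,
                              c(max(0, -lag_window_ms[2]),
                                -lag_window_ms[1]),
                              center_hz, return_profile)
    neg$peak_time_ms <- -neg$peak_time_ms
    if (lag_window_ms[2] < 0) {
      if (return_profile) {
        neg$r <- rev(neg$r); neg$lag_ms <- rev(-neg$lag_ms)
      }
      return(neg)
    }
    pos <- lagged_correlation(x, y, rate_hz, c(0, lag_window_ms[2]),
                              center_hz, return_profile)
    best <- if (neg$peak_amplitude > pos$peak_amplitude) neg else pos
    if (return_profile) {
      best$r <- c(rev(neg$r[-1]), pos$r)
      best$lag_ms <- c(rev(-neg$lag_ms[-1]), pos$lag_ms)
    }
    return(best)
  }
  nx <- length(x); ny <- length(y)
  if (ny < nx) { x <- x[seq_len(ny)]; nx <- ny }
  lag0 <- max(0L, as.integer(round(lag_window_ms[1] / 1000 * rate_hz)))
  lag1 <- as.integer(round(lag_window_ms[2] / 1000 * rate_hz))
  lag1 <- min(lag1, ny - 3L)
  if (lag1 < lag0) stopf("lag window empty after clipping to series length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(peak_amplitude = 0, peak_time_ms = NA_real_, sign = NA_real_,
                low_confidence = TRUE))
  }
  taus <- lag0:lag1
  m <- pmin(nx, ny - taus)            # overlap length per lag
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  Sx <- cx[m]; Sxx <- cx2[m]
  Sy <- cy[taus + m] - c(0, cy)[taus + 1]
  Syy <- cy2[taus + m] - c(0, cy2)[taus + 1]
  Sxy <- cross_sums(x, y, lag1)[taus + 1]
  vx <- Sxx - Sx^2 / m
  vy <- Syy - Sy^2 / m
  num <- Sxy - Sx * Sy / m
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(den > 1e-12, num / den, 0)
  r <- pmin(pmax(r, -1), 1)
  i <- which.max(abs(r))
  low_conf <- if (!is.null(center_hz)) {
    (m[i] / rate_hz) < 2 / center_hz
  } else FALSE
  out <- list(peak_amplitude = abs(r[i]),
              peak_time_ms = taus[i] / rate_hz * 1000,
              sign = sign(r[i]), low_confidence = low_conf)
  if (return_profile) {
    out$r <- r
    out$lag_ms <- taus / rate_hz * 1000
  }
  out
}

#' Delay-embedded CCA correlation (sensitivity cross-check)
#'
#' Embeds `y` with `dim` unit delays and finds the maximal canonical
#' correlation with `x`. For univariate narrowband pairs this optimum
#' coincides with the maximal lagged Pearson correlation searched over the
#' same delays.
#'
#' @param x,y equal-rate series.
#' @param dim embedding dimension (number of delays, default 32).
#' @return maximal canonical correlation in `[0, 1]`.
#' @export
cca_correlation <- function(x, y, dim = 32) {
  n <- min(length(x), length(y)) - dim
  X <- x[seq_len(n)]
  Y <- sapply(0:(dim - 1), function(d) y[seq_len(n) + d])
  cc <- stats::cancor(X, Y)
  cc$cor[1]
}

#' Coherence spectrum of one trial
#'
#' Applies resample -> narrowband (both signals) -> lagged correlation for
#' every grid bin and every requested channel of a single-trial EEG segment.
#'
#' A filter whose bandwidth is 0.2 Hz rings for seconds, so filtering a bare
#' 5 s epoch leaves it dominated by edge transients. The same principle that
#' puts the broadband filter before epoching applies here: pass in the
#' longest EEG segment available (ideally the continuous preprocessed
#' recording around the trial) together with `onset_sample`; the filter bank
#' runs over the whole segment and only the correlation window is restricted
#' to the epoch. With the defaults (`onset_sample = 1`) the function degrades
#' gracefully to filtering the epoch itself.
#'
#' @param flow the trial's [flow_timeseries()] (already reversed for the
#'   reversed condition). The full series is filtered; the correlation uses
#'   its first `duration_s` seconds.
#' @param eeg numeric matrix, channels x samples, at `rate_hz`: the epoch,
#'   or a longer segment containing it.
#' @param rate_hz EEG sampling rate of `eeg`.
#' @param channel_labels labels for the rows of `eeg`.
#' @param grid a [frequency_grid()].
#' @param lag_window_ms lag search window, ms.
#' @param onset_sample sample of `eeg` at which the stimulus starts
#'   (default 1).
#' @param duration_s correlation window length from onset, seconds (default:
#'   as much as both signals cover).
#' @return data.frame with one row per channel x bin: `channel`,
#'   `bin_center_hz`, `peak_amplitude`, `peak_time_ms`, `sign`,
#'   `low_confidence`.
#' @export
coherence_spectrum <- function(flow, eeg, rate_hz, channel_labels,
                               grid = frequency_grid(),
                               lag_window_ms = c(0, 1000),
                               onset_sample = 1, duration_s = NULL) {
  if (is.null(dim(eeg))) eeg <- matrix(eeg, nrow = 1)
  stopifnot(nrow(eeg) == length(channel_labels))
  fres <- resample_flow(flow, rate_hz)
  v <- fres$values - mean(fres$values)
  avail <- min(length(v), ncol(eeg) - onset_sample + 1)
  nwin <- if (is.null(duration_s)) avail else {
    min(avail, as.integer(round(duration_s * rate_hz)))
  }
  if (nwin < 8) stopf("correlation window too short (%d samples)", nwin)
  ewin <- onset_sample:(onset_sample + nwin - 1)
  out <- vector("list", length(grid$centers))
  for (bi in seq_along(grid$centers)) {
    f0 <- grid$centers[bi]
    des <- narrowband_design(f0, grid$bandwidth_hz, rate_hz)
    xf <- zero_phase(des, v)[seq_len(nwin)]
    rows <- lapply(seq_len(nrow(eeg)), function(ch) {
      yf <- zero_phase(des, eeg[ch, ])[ewin]
      pk <- lagged_correlation(xf, yf, rate_hz, lag_window_ms,
                               center_hz = f0)
      data.frame(channel = channel_labels[ch], bin_center_hz = f0,
                 peak_amplitude = pk$peak_amplitude,
                 peak_time_ms = pk$peak_time_ms, sign = pk$sign,
                 low_confidence = pk$low_confidence,
                 stringsAsFactors = FALSE)
    })
    out[[bi]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Coherence spectra of every trial in one preprocessed recording
#'
#' Narrowband-filters each scalp channel once over the continuous recording
#' and each stimulus flow once over its full length, then restricts the
#' lagged correlation to each non-rejected trial's epoch window. Equivalent
#' to per-trial [coherence_spectrum()] with full continuous context, at a
#' fraction of the filtering cost.
#'
#' @param rec continuous preprocessed [eeg_recording()] (with events).
#' @param flows named list of [flow_timeseries()] keyed by `video_id`.
#' @param keep_trials integer vector of event rows to analyse (default: all).
#' @param grid a [frequency_grid()].
#' @param lag_window_ms lag search window, ms.
#' @param window_s epoch window from onset, seconds.
#' @return data.frame as [coherence_spectrum()] plus a `trial` column.
#' @export
recording_coherence <- function(rec, flows, keep_trials = NULL,
                                grid = frequency_grid(),
                                lag_window_ms = c(0, 1000),
                                window_s = c(0, 5)) {
  coherence_engine(rec, flows, keep_trials, grid, lag_window_ms,
                   window_s)$trials
}

#' Trial-aggregated coherence spectrum of one recording (one instance)
#'
#' Computes the lagged-correlation profile of every non-rejected trial and
#' aggregates over trials within each channel x bin cell. Two aggregation
#' modes:
#' \describe{
#'   \item{`peak_mean`}{peak amplitude and peak lag are extracted per trial
#'     and averaged (the default for feature construction).}
#'   \item{`profile_mean`}{the correlation profiles `r(tau)` are averaged
#'     over trials first and the peak extracted from the mean profile.
#'     Uncorrelated trial noise averages out of the profile, so this mode
#'     localises embedded narrowband entrainment far more sharply; it is
#'     the mode used for parameter-recovery validation.}
#' }
#'
#' @inheritParams recording_coherence
#' @param aggregate `"peak_mean"` or `"profile_mean"`.
#' @return data.frame, one row per channel x bin: `channel`,
#'   `bin_center_hz`, `peak_amplitude`, `peak_time_ms`, `sign`,
#'   `low_confidence`, `n_trials`.
#' @export
instance_spectrum <- function(rec, flows, keep_trials = NULL,
                              grid = frequency_grid(),
                              lag_window_ms = c(0, 1000),
                              window_s = c(0, 5),
                              aggregate = c("peak_mean", "profile_mean",
                                            "peak_median")) {
  aggregate <- match.arg(aggregate)
  eng <- coherence_engine(rec, flows, keep_trials, grid, lag_window_ms,
                          window_s,
                          want_profiles = (aggregate == "profile_mean"),
                          want_rows = (aggregate != "profile_mean"))
  if (aggregate == "profile_mean") {
    return(eng$profile_spectrum)
  }
  fun <- if (aggregate == "peak_median") {
    function(z) stats::median(z, na.rm = TRUE)
  } else {
    function(z) mean(z, na.rm = TRUE)
  }
  d <- eng$trials
  agg <- stats::aggregate(
    cbind(peak_amplitude, peak_time_ms) ~ channel + bin_center_hz,
    data = d, FUN = fun, na.action = stats::na.pass)
  agg$n_trials <- length(unique(d$trial))
  agg
}

# shared engine: filters each channel/flow once per bin over the continuous
# recording and correlates per trial window (with post-window context so the
# overlap stays full-length across the lag range)
coherence_engine <- function(rec, flows, keep_trials, grid, lag_window_ms,
                             window_s, want_profiles = FALSE,
                             want_rows = TRUE) {
  scalp <- which(rec$channel_types == "eeg")
  labels <- rec$channel_labels[scalp]
  ev <- rec$events
  if (is.null(keep_trials)) keep_trials <- seq_len(nrow(ev))
  if (length(keep_trials) == 0) {
    stopf("no usable (non-rejected) trials for %s/%s",
          rec$meta$participant %||% "?", rec$meta$condition %||% "?")
  }
  rate <- rec$rate_hz
  nwin <- as.integer(round((window_s[2] - window_s[1]) * rate))
  lagmax <- as.integer(round(lag_window_ms[2] / 1000 * rate))
  vids <- unique(ev$video_id[keep_trials])
  vflt <- list()
  for (vid in vids) {
    if (is.null(flows[[vid]])) stopf("no flow series for video '%s'", vid)
    fr <- resample_flow(flows[[vid]], rate)
    vflt[[vid]] <- fr$values - mean(fr$values)
  }
  nbin <- length(grid$centers)
  rows <- vector("list", nbin)
  prof_rows <- if (want_profiles) vector("list", nbin) else NULL
  for (bi in seq_len(nbin)) {
    f0 <- grid$centers[bi]
    des <- narrowband_design(f0, grid$bandwidth_hz, rate)
    xt <- lapply(vflt, function(v) zero_phase(des, v))
    yt <- lapply(scalp, function(ch) zero_phase(des, rec$data[ch, ]))
    bin_rows <- list()
    psum <- NULL
    for (tr in keep_trials) {
      a <- ev$sample[tr] + as.integer(round(window_s[1] * rate))
      xf <- xt[[ev$video_id[tr]]]
      nw <- min(nwin, length(xf), ncol(rec$data) - a + 1)
      xf <- xf[seq_len(nw)]
      b <- min(a + nw - 1L + lagmax, ncol(rec$data))
      for (k in seq_along(scalp)) {
        pk <- lagged_correlation(xf, yt[[k]][a:b], rate, lag_window_ms,
                                 center_hz = f0,
                                 return_profile = want_profiles)
        if (want_rows) {
          bin_rows[[length(bin_rows) + 1]] <- data.frame(
            trial = tr, channel = labels[k], bin_center_hz = f0,
            peak_amplitude = pk$peak_amplitude,
            peak_time_ms = pk$peak_time_ms, sign = pk$sign,
            low_confidence = pk$low_confidence, stringsAsFactors = FALSE)
        }
        if (want_profiles && !is.null(pk$r)) {
          if (is.null(psum)) {
            psum <- matrix(0, nrow = length(scalp), ncol = length(pk$r))
            lag_grid <- pk$lag_ms
            pn <- integer(length(scalp))
          }
          nr <- min(ncol(psum), length(pk$r))
          psum[k, seq_len(nr)] <- psum[k, seq_len(nr)] + pk$r[seq_len(nr)]
          pn[k] <- pn[k] + 1L
        }
      }
    }
    if (want_rows) rows[[bi]] <- do.call(rbind, bin_rows)
    if (want_profiles && !is.null(psum)) {
      pr <- lapply(seq_along(scalp), function(k) {
        prof <- psum[k, ] / max(pn[k], 1L)
        i <- which.max(abs(prof))
        data.frame(channel = labels[k], bin_center_hz = f0,
                   peak_amplitude = abs(prof[i]),
                   peak_time_ms = lag_grid[i], sign = sign(prof[i]),
                   low_confidence = (nwin / rate) < 2 / f0,
                   n_trials = pn[k], stringsAsFactors = FALSE)
      })
      prof_rows[[bi]] <- do.call(rbind, pr)
    }
  }
  list(trials = if (want_rows) do.call(rbind, rows),
       profile_spectrum = if (want_profiles) do.call(rbind, prof_rows))
}

#' Per-instance coherence spectra for a whole cohort
#'
#' Preprocesses each recording (the full chain of [preprocess()]), computes
#' the coherence spectrum of every non-rejected trial against its video's
#' flow series, and averages peak amplitude and peak time over trials within
#' each participant x condition instance.
#'
#' @param cohort output of [make_cohort()] (or any list with `recordings`,
#'   `flows`, `meta` of the same shape).
#' @param grid a [frequency_grid()].
#' @param lag_window_ms lag search window, ms.
#' @param preproc_opts list of arguments forwarded to [preprocess()].
#' @param aggregate trial aggregation: `"profile"` (peak of the trial-mean
#'   correlation profile, default; see [instance_spectrum()] for why this
#'   estimator is preferred), `"mean"` (mean of per-trial peaks), or
#'   `"median"`.
#' @param progress print a dot per instance.
#' @return data.frame, one row per instance x channel x bin, with
#'   `participant`, `group`, `condition`, `n_trials`, and the spectrum
#'   columns of [coherence_spectrum()].
#' @export
cohort_coherence <- function(cohort, grid = frequency_grid(),
                             lag_window_ms = c(0, 1000),
                             preproc_opts = list(),
                             aggregate = c("profile", "mean", "median"),
                             progress = FALSE) {
  aggregate <- match.arg(aggregate)
  mode <- switch(aggregate, mean = "peak_mean", median = "peak_median",
                 profile = "profile_mean")
  res <- vector("list", nrow(cohort$meta))
  for (i in seq_len(nrow(cohort$meta))) {
    m <- cohort$meta[i, ]
    rec <- cohort$recordings[[i]]
    window_s <- preproc_opts$window_s %||% c(0, 5)
    cont_opts <- preproc_opts[intersect(names(preproc_opts),
                                        c("hp_hz", "lp_hz",
                                          "rolloff_db_oct", "ocular"))]
    prep <- do.call(preprocess_continuous, c(list(rec), cont_opts))
    ep <- reject_amplitude(epoch(prep, window_s),
                           preproc_opts$limit_uv %||% 75)
    keep <- which(!ep$rejection_mask)
    flows <- cohort$flows[[m$condition]]
    agg <- instance_spectrum(prep, flows, keep, grid, lag_window_ms,
                             window_s, aggregate = mode)
    agg$participant <- m$participant
    agg$group <- m$group
    agg$condition <- m$condition
    agg$n_trials <- length(keep)
    res[[i]] <- agg
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, res)
}
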
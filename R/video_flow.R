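# Dense optical flow and the global motion-energy timeseries.
#
# The stimulus-side signal is the per-frame global optical-flow velocity
# magnitude: a dense per-pixel velocity field is estimated between adjacent
# frames, its magnitudes histogrammed per frame, and summed into one scalar
# per frame transition. Horn-Schunck (global smoothness) is the default
# estimator; a dense local least-squares (Lucas-Kanade) estimator is the
# configurable alternative used as a cross-algorithm diagnostic.

#' Dense optical flow between adjacent frames
#'
#' @param frames numeric array `height x width x n_frames`, grayscale in any
#'   consistent intensity scale (RGB arrays `h x w x 3 x n` are converted to
#'   luminance).
#' @param method `"hs"` (Horn-Schunck, default) or `"lk"` (dense
#'   Lucas-Kanade).
#' @param smoothness Horn-Schunck regularisation weight (default 1).
#' @param iterations Horn-Schunck iterations (default 40).
#' @param window Lucas-Kanade neighbourhood half-width in pixels (default 2).
#' @param detrend_luminance subtract the mean temporal gradient per frame
#'   pair so pure global luminance offsets produce no flow (default `TRUE`).
#' @return object of class `flow_field`: list with `magnitudes` (array
#'   `h x w x (n-1)`, pixels/frame), `method`.
#' @export
compute_flow <- function(frames, method = c("hs", "lk"), smoothness = 1,
                         iterations = 40, window = 2,
                         detrend_luminance = TRUE) {
  method <- match.arg(method)
  d <- dim(frames)
  if (length(d) == 4) {           # h x w x 3 x n colour -> luminance
    frames <- 0.299 * frames[, , 1, ] + 0.587 * frames[, , 2, ] +
      0.114 * frames[, , 3, ]
    d <- dim(frames)
  }
  if (length(d) != 3) stopf("frames must be an h x w x n array")
  n <- d[3]
  if (n < 2) stopf("need at least 2 frames, got %d", n)
  mags <- array(0, dim = c(d[1], d[2], n - 1))
  for (i in seq_len(n - 1)) {
    uv <- flow_pair(frames[, , i], frames[, , i + 1], method, smoothness,
                    iterations, window, detrend_luminance)
    mags[, , i] <- sqrt(uv$u^2 + uv$v^2)
  }
  structure(list(magnitudes = mags, method = method), class = "flow_field")
}

# spatial/temporal gradients shared by both estimators (central differences
# averaged over the two frames, as in the classical formulation)
flow_gradients <- function(f1, f2, detrend_luminance) {
  sh <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    m[ri, ci, drop = FALSE]
  }
  fx <- (sh(f1, 0, 1) - sh(f1, 0, -1) + sh(f2, 0, 1) - sh(f2, 0, -1)) / 4
  fy <- (sh(f1, 1, 0) - sh(f1, -1, 0) + sh(f2, 1, 0) - sh(f2, -1, 0)) / 4
  ft <- f2 - f1
  if (detrend_luminance) ft <- ft - mean(ft)
  list(fx = fx, fy = fy, ft = ft)
}

box3 <- function(m) {                     # 3x3 neighbourhood mean
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), ]; dn <- m[c(seq_len(nr - 1) + 1, nr), ]
  s <- m + up + dn
  (s + s[, c(1, seq_len(nc - 1))] + s[, c(seq_len(nc - 1) + 1, nc)]) / 9
}

flow_pair <- function(f1, f2, method, smoothness, iterations, window,
                      detrend_luminance) {
  if (!all(dim(f1) == dim(f2))) stopf("frame dimensions differ")
  g <- flow_gradients(f1, f2, detrend_luminance)
  if (method == "hs") {
    u <- v <- matrix(0, nrow(f1), ncol(f1))
    denom <- smoothness^2 + g$fx^2 + g$fy^2
    for (it in seq_len(iterations)) {
      ub <- box3(u); vb <- box3(v)
      t_ <- (g$fx * ub + g$fy * vb + g$ft) / denom
      u <- ub - g$fx * t_
      v <- vb - g$fy * t_
    }
    list(u = u, v = v)
  } else {
    # dense LK: per-pixel least squares over a (2w+1)^2 neighbourhood,
    # computed with box sums of the gradient products
    wsum <- function(m) {
      for (k in seq_len(window)) m <- box3(m)
      m
    }
    a11 <- wsum(g$fx^2); a12 <- wsum(g$fx * g$fy); a22 <- wsum(g$fy^2)
    b1 <- -wsum(g$fx * g$ft); b2 <- -wsum(g$fy * g$ft)
    det <- a11 * a22 - a12^2
    ok <- det > 1e-9
    u <- ifelse(ok, (a22 * b1 - a12 * b2) / det, 0)
    v <- ifelse(ok, (a11 * b2 - a12 * b1) / det, 0)
    list(u = u, v = v)
  }
}

#' Per-frame optical-flow histogram (velocity spectrum)
#'
#' @param field a `flow_field` from [compute_flow()].
#' @param n_bins number of velocity bins (default 64).
#' @param range velocity range covered; default `[0, p99.9]` of observed
#'   magnitudes (the top permille guards against isolated outlier pixels).
#' @return object of class `flow_histogram`: `bin_edges` (length
#'   `n_bins + 1`) and `counts` (`n_bins x n_transitions`).
#' @export
flow_histogram <- function(field, n_bins = 64, range = NULL) {
  if (n_bins < 1) stopf("n_bins must be >= 1")
  m <- field$magnitudes
  if (length(m) == 0) stopf("empty flow field")
  if (is.null(range)) {
    top <- stats::quantile(m, 0.999, names = FALSE)
    range <- c(0, max(top, 1e-12))
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  nt <- dim(m)[3]
  counts <- vapply(seq_len(nt), function(i) {
    x <- pmin(pmax(m[, , i], range[1]), range[2])
    tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
             nbins = n_bins)
  }, numeric(n_bins))
  structure(list(bin_edges = edges,
                 counts = matrix(counts, nrow = n_bins)),
            class = "flow_histogram")
}

#' Global optical-flow magnitude timeseries
#'
#' One scalar per frame transition: the sum over pixels of the velocity
#' magnitude (the count-weighted velocity-bin sum in the fine-bin limit;
#' summing raw bin counts would be a constant equal to the pixel count, so
#' the count-weighted reading is used).
#'
#' @param field a `flow_field` from [compute_flow()].
#' @param frame_rate_hz frame rate of the source video.
#' @param source_id stimulus identifier.
#' @return a [flow_timeseries()] of length `n_frames - 1`.
#' @export
global_flow <- function(field, frame_rate_hz = 30,
                        source_id = NA_character_) {
  vals <- apply(field$magnitudes, 3, sum)
  flow_timeseries(vals, frame_rate_hz, source_id)
}

#' Extract the flow timeseries of a video in one call
#'
#' `global_flow(compute_flow(frames))` with shared arguments.
#'
#' @inheritParams compute_flow
#' @inheritParams global_flow
#' @return a [flow_timeseries()].
#' @export
video_flow <- function(frames, frame_rate_hz = 30,
                       source_id = NA_character_, method = "hs", ...) {
  global_flow(compute_flow(frames, method = method, ...), frame_rate_hz,
              source_id)
}

#' Write / read a flow timeseries as two-column CSV
#'
#' Columns `frame_index` (1-based transition index) and `magnitude`.
#'
#' @param flow a [flow_timeseries()].
#' @param path file path.
#' @param frame_rate_hz frame rate to attach on read.
#' @return `read_flow_csv` returns a [flow_timeseries()].
#' @export
write_flow_csv <- function(flow, path) {
  utils::write.csv(data.frame(frame_index = seq_along(flow$values),
                              magnitude = flow$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path, frame_rate_hz = 30) {
  d <- utils::read.csv(path)
  flow_timeseries(d$magnitude, frame_rate_hz,
                  source_id = sub("[.]csv$", "", basename(path)))
}
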
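# Region x frequency feature matrices.
#
# Channel-level coherence spectra are averaged over the four scalp regions,
# then assembled into an instances x features matrix: one amplitude and one
# timing feature per region x bin (4 x 62 x 2 = 496 features on the default
# grid), one row per participant x condition instance. Columns are z-scaled;
# scaling statistics can be fit on a training subset and reused on held-out
# rows so no information leaks across the split.

#' Average channel-level coherence over scalp regions
#'
#' Per region x bin, amplitude is the mean of member-channel peak amplitudes
#' and time the mean of member-channel peak lags (plain means: lags are
#' durations, not phases).
#'
#' @param spec data.frame of channel-level coherence (columns `channel`,
#'   `bin_center_hz`, `peak_amplitude`, `peak_time_ms`, as produced by
#'   [coherence_spectrum()] or one instance of [cohort_coherence()]).
#' @param map region map, as from [region_map()].
#' @return data.frame with `region`, `bin_center_hz`, `peak_amplitude`,
#'   `peak_time_ms`.
#' @export
region_average <- function(spec, map = region_map()) {
  out <- list()
  for (r in names(map)) {
    chans <- map[[r]]
    missing <- setdiff(chans, unique(spec$channel))
    if (length(missing) == length(chans)) {
      stopf("region '%s' has no channels available in the spectrum", r)
    }
    sub <- spec[spec$channel %in% chans, ]
    agg <- stats::aggregate(
      cbind(peak_amplitude, peak_time_ms) ~ bin_center_hz,
      data = sub, FUN = mean, na.action = stats::na.pass)
    agg$region <- r
    out[[r]] <- agg[, c("region", "bin_center_hz", "peak_amplitude",
                        "peak_time_ms")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Canonical feature-column names
#'
#' Amplitude block first, then time block; within a block regions in the
#' fixed order anterior, posterior, left, right (region-major), bins
#' ascending (bin-minor). This ordering is part of the file format so ranked
#' feature indices are comparable across runs.
#'
#' @param bins bin centres, Hz.
#' @param regions region names in canonical order.
#' @return character vector of `type_region_binHz` names.
#' @export
feature_names <- function(bins, regions = REGIONS) {
  unlist(lapply(c("amplitude", "time"), function(ty) {
    unlist(lapply(regions, function(r) {
      sprintf("%s_%s_%.1fHz", ty, r, bins)
    }))
  }))
}

#' Parse canonical feature names back into their components
#' @param names character vector of feature names.
#' @return data.frame with `parameter` (`amplitude`/`time`), `region`,
#'   `bin_center_hz`.
#' @export
parse_feature_names <- function(names) {
  m <- regmatches(names,
                  regexec("^(amplitude|time)_([a-z]+)_([0-9.]+)Hz$", names))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stopf("unparseable feature name '%s'", names[bad][1])
  data.frame(parameter = vapply(m, `[`, character(1), 2),
             region = vapply(m, `[`, character(1), 3),
             bin_center_hz = as.numeric(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Assemble the instances x features matrix
#'
#' @param region_spectra list of per-instance region-level spectra (each as
#'   returned by [region_average()]), in any order.
#' @param instances data.frame aligned with `region_spectra`: `participant`,
#'   `group`, `condition`. Rows of the result are sorted by
#'   (group, participant, condition).
#' @return object of class `feature_matrix`: `values` (instances x
#'   features), `feature_names`, `instances`, `scaling` (`NULL` until
#'   [zscale()]).
#' @export
assemble <- function(region_spectra, instances) {
  stopifnot(length(region_spectra) == nrow(instances))
  bins <- sort(unique(region_spectra[[1]]$bin_center_hz))
  fn <- feature_names(bins)
  ord <- order(instances$group, instances$participant, instances$condition)
  vals <- matrix(NA_real_, nrow = length(ord), ncol = length(fn),
                 dimnames = list(NULL, fn))
  for (k in seq_along(ord)) {
    sp <- region_spectra[[ord[k]]]
    key <- sprintf("%s_%.1fHz", sp$region, sp$bin_center_hz)
    amp <- stats::setNames(sp$peak_amplitude, key)
    tim <- stats::setNames(sp$peak_time_ms, key)
    want <- as.vector(t(outer(REGIONS, bins,
                              function(r, b) sprintf("%s_%.1fHz", r, b))))
    if (anyNA(match(want, key))) {
      miss <- setdiff(want, key)[1]
      stopf("instance %d is missing cell %s", ord[k], miss)
    }
    vals[k, ] <- c(amp[want], tim[want])
  }
  if (anyNA(vals)) stopf("missing values in assembled feature matrix")
  structure(list(values = vals, feature_names = fn,
                 instances = instances[ord, , drop = FALSE],
                 scaling = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$scaling)) "" else " (z-scaled)"))
  invisible(x)
}

#' Z-scale feature columns
#'
#' Columns are centred and scaled to unit standard deviation using
#' statistics computed from `fit_rows` only; the statistics are stored so
#' they can be re-applied to held-out rows (see [apply_scaling()]). A
#' zero-variance column is scaled to 0 with a warning, never divided by
#' zero.
#'
#' @param fm a `feature_matrix`.
#' @param fit_rows integer rows used to fit the scaling (default: all rows —
#'   note that in any train/test context the caller must restrict this to
#'   training rows).
#' @return the `feature_matrix` with scaled `values` and `scaling` set to
#'   `list(mean, sd)`.
#' @export
zscale <- function(fm, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(fm$values))
  if (length(fit_rows) == 0) stopf("fit_rows is empty")
  mu <- colMeans(fm$values[fit_rows, , drop = FALSE])
  sd_ <- apply(fm$values[fit_rows, , drop = FALSE], 2, stats::sd)
  zero <- sd_ < 1e-12 | is.na(sd_)
  if (any(zero)) {
    warnf("%d zero-variance column(s) scaled to 0", sum(zero))
    sd_[zero] <- Inf
  }
  fm$values <- sweep(sweep(fm$values, 2, mu), 2, sd_, `/`)
  fm$scaling <- list(mean = mu, sd = sd_)
  fm
}

#' Apply previously fitted scaling statistics to a matrix
#'
#' @param values numeric matrix with the same columns as the matrix the
#'   scaling was fit on.
#' @param scaling `list(mean, sd)` from [zscale()].
#' @return scaled matrix.
#' @export
apply_scaling <- function(values, scaling) {
  sweep(sweep(values, 2, scaling$mean), 2, scaling$sd, `/`)
}

#' Write / read a feature matrix as CSV plus JSON sidecar
#'
#' The CSV holds instance labels and feature columns; the sidecar records
#' the canonical column order, any scaling parameters, and a content hash.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path; the sidecar is `path` with `.json` appended.
#' @return `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  d <- cbind(fm$instances, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE)
  sidecar <- list(
    feature_names = fm$feature_names,
    scaling = fm$scaling,
    content_hash = sprintf("%.0f", sum(abs(fm$values)) * 1e6))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fn <- side$feature_names
  structure(list(values = as.matrix(d[, fn, drop = FALSE]),
                 feature_names = fn,
                 instances = d[, setdiff(names(d), fn), drop = FALSE],
                 scaling = side$scaling),
            class = "feature_matrix")
}

#' Slice a feature matrix to a parameter subset
#'
#' @param fm a `feature_matrix`.
#' @param subset `"amplitude_and_time"`, `"amplitude_only"`, or
#'   `"time_only"`.
#' @return the sliced `feature_matrix`.
#' @export
feature_subset <- function(fm, subset = c("amplitude_and_time",
                                          "amplitude_only", "time_only")) {
  subset <- match.arg(subset)
  if (subset == "amplitude_and_time") return(fm)
  want <- if (subset == "amplitude_only") "^amplitude_" else "^time_"
  keep <- grepl(want, fm$feature_names)
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$feature_names <- fm$feature_names[keep]
  if (!is.null(fm$scaling)) {
    fm$scaling <- list(mean = fm$scaling$mean[keep],
                       sd = fm$scaling$sd[keep])
  }
  fm
}
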
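# BrainVision triplet IO.
#
# The interchange format is the BrainVision Core Data Format 1.0 triplet:
# an INI-style text header (.vhdr) describing the binary layout, a text
# marker file (.vmrk) with stimulus events, and a raw binary data file
# (.eeg), written here as IEEE_FLOAT_32 multiplexed (the float dialect is
# stated in the header; INT_16 with per-channel resolution is accepted on
# read).

#' Write an EEG recording as a BrainVision triplet
#'
#' @param rec an [eeg_recording()].
#' @param basename path without extension; `.vhdr`, `.vmrk`, `.eeg` are
#'   appended.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nm <- basename(basename)
  ch_lines <- vapply(seq_along(rec$channel_labels), function(i) {
    sprintf("Ch%d=%s,,1,µV", i, rec$channel_labels[i])
  }, character(1))
  header <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", nm),
    sprintf("MarkerFile=%s.vmrk", nm),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%d", as.integer(round(1e6 / rec$rate_hz))),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    ch_lines)
  writeLines(header, vhdr, useBytes = TRUE)
  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", nm),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events)) {
    mk <- c(mk, vapply(seq_len(nrow(rec$events)), function(i) {
      sprintf("Mk%d=Stimulus,S%3d,%d,1,0", i + 1,
              rec$events$code[i], rec$events$sample[i])
    }, character(1)))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", trimws(ln))
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Parses the `.vhdr` header for binary format (IEEE_FLOAT_32 or INT_16
#' with resolutions), orientation, rate, and channel order; reads data and
#' stimulus markers.
#'
#' @param vhdr_path path to the `.vhdr` file.
#' @return an [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  ini <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stopf("no [Common Infos] section in %s", vhdr_path)
  if (!identical(ci$DataFormat, "BINARY")) {
    stopf("unsupported DataFormat '%s'", ci$DataFormat %||% "?")
  }
  orientation <- ci$DataOrientation %||% "MULTIPLEXED"
  n_ch <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  chs <- ini[["Channel Infos"]]
  labels <- character(n_ch); resol <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    parts <- strsplit(chs[[sprintf("Ch%d", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) {
      resol[i] <- as.numeric(parts[3])
    }
  }
  dir <- dirname(vhdr_path)
  fmt <- bi$BinaryFormat %||% "IEEE_FLOAT_32"
  eeg_path <- file.path(dir, ci$DataFile)
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = sz / 2, size = 2, endian = "little",
            signed = TRUE)
  } else stopf("unsupported BinaryFormat '%s'", fmt)
  n_samp <- length(raw_vals) %/% n_ch
  data <- if (orientation == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_ch, ncol = n_samp)
  } else {
    t(matrix(raw_vals, nrow = n_samp, ncol = n_ch))
  }
  data <- data * resol
  events <- data.frame(sample = integer(), code = integer(),
                       video_id = character())
  vmrk_path <- file.path(dir, ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk_path)) {
    mi <- parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    rows <- lapply(mi, function(v) {
      parts <- strsplit(v, ",")[[1]]
      if (!identical(parts[1], "Stimulus")) return(NULL)
      code <- as.integer(gsub("[^0-9]", "", parts[2]))
      data.frame(sample = as.integer(parts[3]), code = code,
                 video_id = sprintf("vid%02d", code))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) events <- do.call(rbind, rows)
  }
  types <- ifelse(labels %in% montage_aux()$mastoids, "mastoid",
                  ifelse(labels %in% unlist(montage_aux()[c("heog", "veog")]),
                         "eog", "eeg"))
  eeg_recording(data, rate, labels, types, events)
}
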
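#' Scalp region-of-interest map
#'
#' The four scalp regions over which channel-level coherence is averaged:
#' anterior, posterior, left, and right, each a fixed set of five 10/20
#' electrodes.
#'
#' @return named list of character vectors of channel labels.
#' @export
region_map <- function() {
  list(
    anterior  = c("F3", "F4", "Fz", "FC1", "FC2"),
    posterior = c("P7", "P8", "P3", "P4", "Pz"),
    left      = c("C3", "FC5", "T7", "CP1", "CP5"),
    right     = c("C4", "FC6", "T8", "CP2", "CP6")
  )
}

REGIONS <- c("anterior", "posterior", "left", "right")

#' Map a channel label to its scalp region
#'
#' @param label channel label.
#' @param map region map, as from [region_map()].
#' @return region name, or `NA_character_` if the channel is in no region.
#' @export
channel_region <- function(label, map = region_map()) {
  for (r in names(map)) if (label %in% map[[r]]) return(r)
  NA_character_
}

#' Standard 26-channel 10/20 montage used throughout
#'
#' Scalp labels of the recording montage; mastoid and EOG channels are listed
#' separately by [montage_aux()].
#'
#' @return character vector of 26 scalp labels.
#' @export
montage_scalp <- function() {
  c("Fz", "Cz", "Pz", "Oz", "F3", "F4", "F7", "F8", "FC1", "FC2",
    "FC5", "FC6", "T7", "T8", "C3", "C4", "CP1", "CP2", "CP5", "CP6",
    "P3", "P7", "P4", "P8", "O1", "O2")
}

#' Auxiliary (non-scalp) channels: mastoids and EOG pairs
#' @return named list with `mastoids`, `heog`, `veog` label pairs.
#' @export
montage_aux <- function() {
  list(mastoids = c("M1", "M2"),
       heog = c("HEOGL", "HEOGR"),
       veog = c("VEOGU", "VEOGL"))
}
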
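#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (text header), `<basename>.vmrk` (text
#' markers) and `<basename>.eeg` (32-bit IEEE float, multiplexed,
#' little-endian). Block onsets are stored as stimulus markers
#' `S <brightness code + 3>` (1..5) with the block duration in the marker
#' length field.
#'
#' @param rec An `eeg_recording` in microvolts.
#' @param basename Path without extension.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(basename)
  nch <- nrow(rec$data)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by ssvepmod",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rownames(rec$data))
  )
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = TRUE)

  mk <- rec$markers
  dur <- if (!is.null(mk$duration)) round(mk$duration * rec$srate) else
    rep(1L, nrow(mk))
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,S%3d,%d,%d,0",
            seq_len(nrow(mk)) + 1L, mk$brightness + 3L, mk$sample, dur)
  )
  writeLines(mrk, paste0(basename, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(basename)
}

#' Read a BrainVision triplet
#'
#' Supports the subset written by [write_brainvision()]: multiplexed
#' IEEE_FLOAT_32 binary data with stimulus markers carrying brightness
#' codes.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  field <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  if (field("DataFormat") != "BINARY" ||
      field("DataOrientation") != "MULTIPLEXED" ||
      field("BinaryFormat") != "IEEE_FLOAT_32")
    stop("only multiplexed IEEE_FLOAT_32 BrainVision files are supported")
  nch <- as.integer(field("NumberOfChannels"))
  srate <- 1e6 / as.numeric(field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  stopifnot(length(labels) == nch)

  dir <- dirname(vhdr)
  eeg_path <- file.path(dir, field("DataFile"))
  sz <- file.info(eeg_path)$size
  n_samp <- as.integer(sz / 4 / nch)
  con <- file(eeg_path, "rb")
  raw <- readBin(con, numeric(), n = nch * n_samp, size = 4,
                 endian = "little")
  close(con)
  data <- matrix(raw, nrow = nch, dimnames = list(labels, NULL))

  mlines <- readLines(file.path(dir, field("MarkerFile")), encoding = "UTF-8")
  stim <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
  markers <- data.frame(
    sample = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    block = seq_along(parts),
    brightness = vapply(parts, function(p)
      as.integer(sub("^S\\s*", "", p[2])) - 3L, integer(1)),
    duration = vapply(parts, function(p) as.integer(p[4]), integer(1)) / srate
  )
  eeg_recording(data, srate, markers, reference = "common",
                log = sprintf("read %s", vhdr))
}

#' Write the participant covariate table as CSV
#'
#' Columns: `participant`, `menstrual_pain` (VAS 0-100),
#' `somatic_symptoms` (symptom sum), `bladder_pain` (VAS 0-100), plus one
#' `rating_<code>` column per brightness code when ratings are supplied.
#'
#' @param covariates Participant table.
#' @param path Output CSV path.
#' @param ratings Optional long ratings tibble (participant, brightness,
#'   rating).
#' @return `path`, invisibly.
#' @export
write_participants_csv <- function(covariates, path, ratings = NULL) {
  out <- covariates
  if (!is.null(ratings)) {
    wide <- tidyr::pivot_wider(ratings, names_from = "brightness",
                               values_from = "rating",
                               names_prefix = "rating_")
    out <- dplyr::left_join(out, wide, by = "participant")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
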
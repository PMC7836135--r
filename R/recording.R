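#' Construct a continuous EEG recording object
#'
#' Container for continuous multi-channel EEG with stimulation-block
#' markers. Data are stored channels x samples in microvolts.
#'
#' @param data Numeric matrix, channels x samples, with channel labels as
#'   rownames.
#' @param srate Sampling rate in Hz.
#' @param markers Data frame with columns `sample` (1-based onset sample of
#'   each stimulation block), `block` (integer id) and `brightness`
#'   (mean-centered brightness code, -2..2).
#' @param reference Label of the reference scheme (e.g. `"common"`,
#'   `"avg-mastoid"`).
#' @param units Data units; `"uV"` for voltage data.
#' @param log Character vector of processing-stage messages.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, markers, reference = "common",
                          units = "uV", log = character()) {
  stopifnot(is.matrix(data), !is.null(rownames(data)), srate > 0)
  markers <- as.data.frame(markers)
  stopifnot(all(c("sample", "block", "brightness") %in% names(markers)))
  if (is.unsorted(markers$sample, strictly = TRUE))
    stop("marker sample indices must be strictly increasing")
  if (any(markers$sample < 1) || any(markers$sample > ncol(data)))
    stop("marker sample indices outside the recording")
  structure(
    list(data = data, srate = srate, markers = markers,
         reference = reference, units = units, log = log),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s, %d markers\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
    x$reference, nrow(x$markers)
  ))
  invisible(x)
}

log_stage <- function(rec, msg) {
  rec$log <- c(rec$log, msg)
  rec
}

#' Construct an epoch-set object
#'
#' @param epochs Numeric array, epoch x channel x sample.
#' @param meta Data frame with one row per epoch: `epoch`, `block`,
#'   `brightness`, `kept`.
#' @param srate Sampling rate in Hz.
#' @param window Epoch length in seconds.
#' @param channel_labels Channel labels matching dim 2 of `epochs`.
#' @param units `"uV"` before, `"CSD"` after, the surface Laplacian.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, meta, srate, window, channel_labels,
                       units = "uV") {
  stopifnot(length(dim(epochs)) == 3L,
            dim(epochs)[2] == length(channel_labels),
            dim(epochs)[3] == round(window * srate),
            nrow(meta) == dim(epochs)[1])
  structure(
    list(epochs = epochs, meta = tibble::as_tibble(meta), srate = srate,
         window = window, channel_labels = channel_labels, units = units),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs (%d kept) x %d channels x %d samples @ %g Hz [%s]\n",
    nrow(x$meta), sum(x$meta$kept), dim(x$epochs)[2], dim(x$epochs)[3],
    x$srate, x$units
  ))
  invisible(x)
}
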
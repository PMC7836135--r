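#' Re-reference to the average of the mastoids
#'
#' Subtracts the mean of the left and right mastoid channels from every
#' scalp channel, per sample, and drops the mastoids from the channel set.
#'
#' @param rec An `eeg_recording`.
#' @param mastoids Labels of the two mastoid channels.
#' @return The re-referenced recording.
#' @export
rereference_mastoids <- function(rec, mastoids = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(mastoids, rownames(rec$data))
  if (length(missing) > 0)
    stop("mastoid channel(s) not present: ", paste(missing, collapse = ", "))
  ref <- colMeans(rec$data[mastoids, , drop = FALSE])
  keep <- setdiff(rownames(rec$data), mastoids)
  rec$data <- sweep(rec$data[keep, , drop = FALSE], 2, ref, "-")
  rec$reference <- "avg-mastoid"
  log_stage(rec, "re-referenced to average mastoids")
}

# Hamming windowed-sinc high-pass kernel by spectral inversion of a
# unit-DC-gain low-pass. cutoff is the -6 dB (half-amplitude) point; the
# filter order follows the Hamming transition-width rule 3.3/N.
design_highpass_sinc <- function(fs, cutoff = 1, transition = 2) {
  L <- ceiling(3.3 * fs / transition)
  if (L %% 2 == 0) L <- L + 1
  M <- (L - 1) / 2
  k <- -M:M
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  lp <- 2 * (cutoff / fs) * sinc(2 * (cutoff / fs) * k) *
    (0.54 + 0.46 * cos(2 * pi * k / (L - 1)))
  lp <- lp / sum(lp)
  hp <- -lp
  hp[M + 1] <- hp[M + 1] + 1
  hp
}

# Zero-phase application of an odd-length linear-phase FIR: reflect-pad by
# the group delay, filter causally (FFT convolution), trim the delay.
apply_fir_zerophase <- function(x, h) {
  M <- (length(h) - 1) / 2
  n <- length(x)
  if (n <= 2 * M) stop("record shorter than the filter order")
  xp <- c(2 * x[1] - rev(x[2:(M + 1)]),
          x,
          2 * x[n] - rev(x[(n - M):(n - 1)]))
  y <- signal::fftfilt(h, c(xp, numeric(M)))
  y[(2 * M + 1):(2 * M + n)]
}

#' High-pass filter a recording (windowed-sinc FIR, zero phase)
#'
#' 1 Hz Hamming windowed-sinc finite impulse response high-pass with a
#' -6 dB half-amplitude point at `cutoff` and the stated transition
#' bandwidth, applied with zero phase (linear-phase kernel, group delay
#' compensated).
#'
#' @param rec An `eeg_recording`.
#' @param cutoff -6 dB cutoff frequency, Hz.
#' @param transition Transition bandwidth, Hz (sets the filter order via
#'   the Hamming design rule).
#' @return The filtered recording.
#' @export
highpass_fir <- function(rec, cutoff = 1, transition = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$srate <= 2 * (cutoff + transition))
    stop("sampling rate too low for the requested cutoff/transition")
  h <- design_highpass_sinc(rec$srate, cutoff, transition)
  rec$data <- t(apply(rec$data, 1, apply_fir_zerophase, h = h))
  log_stage(rec, sprintf("high-pass FIR %g Hz (transition %g Hz, order %d)",
                         cutoff, transition, length(h) - 1))
}

# Fourier-domain resampling of a real signal, with an optional brick-wall
# guard band below the output Nyquist.
resample_fourier <- function(x, n_new, guard = 1) {
  n <- length(x)
  if (n_new == n && guard >= 1) return(x)
  X <- stats::fft(x)
  Ko <- floor(n / 2)
  Kn <- floor(n_new / 2)
  K <- min(Ko, Kn)
  Y <- complex(n_new)
  Y[1] <- X[1]
  if (K >= 2) {
    idx <- 2:K
    Y[idx] <- X[idx]
    Y[n_new - idx + 2] <- Conj(X[idx])
  }
  if (n_new < n) {
    if (n_new %% 2 == 0) Y[Kn + 1] <- complex(real = Re(X[Kn + 1]))
  } else if (n %% 2 == 0 && n_new > n) {
    Y[Ko + 1] <- X[Ko + 1] / 2
    Y[n_new - Ko + 1] <- Conj(X[Ko + 1] / 2)
  }
  if (guard < 1) {
    kmax <- floor(guard * Kn)
    if (kmax + 2 <= Kn + 1) Y[(kmax + 2):(Kn + 1)] <- 0
    hi <- n_new - ((kmax + 1):Kn) + 2
    Y[hi[hi <= n_new & hi >= 1]] <- 0
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a recording
#'
#' Fourier-domain resampling to the target rate. Content above 90% of the
#' new Nyquist frequency is removed as an anti-alias guard band; the
#' steady-state frequency band of interest (25 Hz) is preserved exactly.
#' Marker indices are remapped to the nearest new sample.
#'
#' @param rec An `eeg_recording`.
#' @param target Target sampling rate, Hz.
#' @return The resampled recording.
#' @export
downsample <- function(rec, target = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target > rec$srate) stop("target rate exceeds the original rate")
  n <- ncol(rec$data)
  n_new <- round(n * target / rec$srate)
  rec$data <- t(apply(rec$data, 1, resample_fourier, n_new = n_new,
                      guard = 0.9))
  rec$markers$sample <- pmin(pmax(
    round((rec$markers$sample - 1) * target / rec$srate) + 1, 1), n_new)
  rec$srate <- target
  log_stage(rec, sprintf("downsampled to %g Hz (n=%d)", target, n_new))
}

#' Remove line noise with a band-stop filter
#'
#' Second-order Butterworth band-stop (+/- 2 Hz around the line frequency),
#' applied forward-backward for zero phase. The stimulation band (25 Hz)
#' is untouched (<0.01 dB change).
#'
#' @param rec An `eeg_recording`.
#' @param freq Line frequency, Hz.
#' @param width Half-width of the stop band, Hz.
#' @return The filtered recording.
#' @export
notch_line <- function(rec, freq = 60, width = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (freq >= rec$srate / 2) stop("line frequency at or above Nyquist")
  bt <- signal::butter(2, c(freq - width, freq + width) / (rec$srate / 2),
                       type = "stop")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bt, x)))
  log_stage(rec, sprintf("band-stop %g +/- %g Hz", freq, width))
}

#' Preprocess a continuous recording
#'
#' Fixed-order chain: average-mastoid re-reference, 1 Hz windowed-sinc
#' high-pass, Fourier resampling to the analysis rate, line-noise
#' band-stop. Each stage is appended to the recording log.
#'
#' @param rec An `eeg_recording`.
#' @param mastoids Mastoid channel labels (skipped if absent and
#'   `require_mastoids = FALSE`).
#' @param cutoff,transition High-pass parameters, Hz.
#' @param target_rate Analysis sampling rate, Hz.
#' @param line_freq Line frequency, Hz.
#' @param require_mastoids Error if the mastoid channels are missing.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, mastoids = c("M1", "M2"),
                                 cutoff = 1, transition = 2,
                                 target_rate = 256, line_freq = 60,
                                 require_mastoids = FALSE) {
  if (all(mastoids %in% rownames(rec$data)) || require_mastoids)
    rec <- rereference_mastoids(rec, mastoids)
  rec <- highpass_fir(rec, cutoff, transition)
  rec <- downsample(rec, target_rate)
  notch_line(rec, line_freq)
}

#' Extract overlapping epochs from the stimulation blocks
#'
#' Slides a `window`-second window in steps of `window - overlap` seconds
#' from each block onset marker; the final partial window is discarded, so
#' a 20-s block with 2-s windows and 1-s overlap yields 19 epochs. Epochs
#' start exactly at the block onset sample.
#'
#' @param rec A preprocessed `eeg_recording`.
#' @param window Epoch length, seconds.
#' @param overlap Overlap between consecutive epochs, seconds.
#' @return An `eeg_epochs` object; epoch metadata carries the block id and
#'   brightness code. Blocks shorter than one window contribute zero epochs
#'   (with a warning).
#' @export
epoch_blocks <- function(rec, window = 2, overlap = 1) {
  stopifnot(inherits(rec, "eeg_recording"), window > overlap, overlap >= 0)
  fs <- rec$srate
  wlen <- round(window * fs)
  step <- round((window - overlap) * fs)
  n <- ncol(rec$data)
  mk <- rec$markers
  # a block spans from its onset to the next marker (or end of record),
  # bounded by its stated duration when the markers carry one -- padding
  # between blocks is never epoched
  block_len <- c(diff(mk$sample), n - mk$sample[nrow(mk)] + 1L)
  if (!is.null(mk$duration))
    block_len <- pmin(block_len, round(mk$duration * fs))

  slices <- list()
  meta <- list()
  e <- 0L
  for (b in seq_len(nrow(mk))) {
    avail <- min(block_len[b], n - mk$sample[b] + 1)
    n_ep <- if (avail < wlen) 0L else (avail - wlen) %/% step + 1L
    if (n_ep == 0L)
      warning(sprintf("block %d shorter than the epoch window; zero epochs",
                      mk$block[b]))
    for (k in seq_len(n_ep)) {
      s0 <- mk$sample[b] + (k - 1L) * step
      e <- e + 1L
      slices[[e]] <- rec$data[, s0:(s0 + wlen - 1L), drop = FALSE]
      meta[[e]] <- data.frame(epoch = e, block = mk$block[b],
                              brightness = mk$brightness[b], kept = TRUE)
    }
  }
  if (e == 0L) stop("no epochs could be extracted")
  arr <- array(0, dim = c(e, nrow(rec$data), wlen))
  for (i in seq_len(e)) arr[i, , ] <- slices[[i]]
  eeg_epochs(arr, do.call(rbind, meta), srate = fs, window = window,
             channel_labels = rownames(rec$data), units = rec$units)
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' Marks as rejected any epoch whose absolute value exceeds the threshold
#' on any channel at any sample. Applied on voltage epochs, before the
#' surface Laplacian. Rejection counts are recorded in the
#' `rejection_counts` attribute; a block losing all of its epochs is listed
#' in the `missing_blocks` attribute so the modeling stage can propagate
#' the missing value.
#'
#' @param eset An `eeg_epochs` object in microvolts.
#' @param threshold Rejection threshold, microvolts.
#' @return The epoch set with updated `kept` flags.
#' @export
reject_epochs <- function(eset, threshold = 100) {
  stopifnot(inherits(eset, "eeg_epochs"))
  if (eset$units != "uV")
    warning("amplitude rejection is defined on voltage (uV) epochs")
  peak <- apply(abs(eset$epochs), 1, max)
  eset$meta$kept <- peak <= threshold
  counts <- stats::aggregate(kept ~ block, data = eset$meta,
                             FUN = function(k) sum(!k))
  names(counts) <- c("block", "n_rejected")
  attr(eset, "rejection_counts") <- counts
  gone <- vapply(split(eset$meta$kept, eset$meta$block),
                 function(k) !any(k), logical(1))
  attr(eset, "missing_blocks") <- as.integer(names(gone))[gone]
  eset
}

#' Subset an epoch set by epoch index
#'
#' @param eset An `eeg_epochs` object.
#' @param idx Epoch indices to keep.
#' @return The subset epoch set (rejection attributes are dropped).
#' @export
subset_epochs <- function(eset, idx) {
  eset$epochs <- eset$epochs[idx, , , drop = FALSE]
  eset$meta <- eset$meta[idx, ]
  for (a in c("rejection_counts", "missing_blocks")) attr(eset, a) <- NULL
  eset
}
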
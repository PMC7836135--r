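#' One-sided Hamming-tapered periodogram of a single epoch channel
#'
#' FFT power spectral density with a Hamming taper and window-power
#' normalization (density scaling, power per Hz): interior bins carry twice
#' the two-sided power, DC and Nyquist are not doubled. A 2-second epoch at
#' 256 Hz gives 0.5 Hz bin spacing, so the 25 Hz stimulation frequency
#' falls exactly on a bin.
#'
#' @param x Numeric vector, one epoch of one channel (even length).
#' @param fs Sampling rate, Hz.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
psd_epoch <- function(x, fs) {
  n <- length(x)
  if (n %% 2 != 0) stop("epoch length must be even")
  if (anyNA(x)) stop("NaN/NA samples in epoch")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- stats::fft(x * w)
  p <- Mod(X[1:(n / 2 + 1)])^2 / (fs * sum(w^2))
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  list(freq = (0:(n / 2)) * fs / n, psd = p)
}

#' Stimulation-frequency power of an epoch set, in dB
#'
#' Averages the linear power at the `f0` bin across kept epochs, then
#' converts to decibels (`10 log10`). Averaging before the log is the
#' standard PSD-averaging order; set `db_first = TRUE` to average
#' per-epoch dB values instead.
#'
#' @param eset An `eeg_epochs` object (typically one stimulation block,
#'   post-Laplacian).
#' @param f0 Target frequency, Hz; must fall on an FFT bin.
#' @param db_first Average per-epoch dB rather than linear power.
#' @return Named numeric vector of dB power per electrode. If no epoch is
#'   kept, `NA` for every electrode.
#' @export
ssvep_power <- function(eset, f0 = 25, db_first = FALSE) {
  stopifnot(inherits(eset, "eeg_epochs"))
  keep <- which(eset$meta$kept)
  nch <- dim(eset$epochs)[2]
  if (length(keep) == 0)
    return(stats::setNames(rep(NA_real_, nch), eset$channel_labels))
  nsamp <- dim(eset$epochs)[3]
  df <- eset$srate / nsamp
  bin <- f0 / df + 1
  if (abs(bin - round(bin)) > 1e-8)
    stop(sprintf("f0 = %g Hz does not fall on a %g Hz bin grid", f0, df))
  bin <- round(bin)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nsamp - 1)) / (nsamp - 1))
  norm <- eset$srate * sum(w^2)
  ex <- exp(-2i * pi * (bin - 1) * (0:(nsamp - 1)) / nsamp)
  vals <- matrix(NA_real_, nrow = length(keep), ncol = nch)
  for (i in seq_along(keep)) {
    seg <- eset$epochs[keep[i], , ] * rep(w, each = nch)
    X <- seg %*% ex
    p <- Mod(X)^2 / norm
    if (bin > 1 && bin < nsamp / 2 + 1) p <- 2 * p
    vals[i, ] <- p
  }
  out <- if (db_first) colMeans(10 * log10(vals)) else
    10 * log10(colMeans(vals))
  stats::setNames(as.numeric(out), eset$channel_labels)
}

#' Assemble the PSD table across participants
#'
#' For every participant's (post-Laplacian) epoch set, averages the
#' stimulation-frequency power across kept epochs within each brightness
#' block and emits one long-format row per participant x electrode x
#' brightness. Blocks with zero kept epochs are omitted and flagged in the
#' `missing_blocks` attribute.
#'
#' @param esets Named list (participant id -> `eeg_epochs`).
#' @param f0 Stimulation frequency, Hz.
#' @param db_first Passed to [ssvep_power()].
#' @return A tibble (participant, electrode, brightness, psd_db,
#'   n_epochs).
#' @export
build_psd_table <- function(esets, f0 = 25, db_first = FALSE) {
  stopifnot(is.list(esets), !is.null(names(esets)))
  rows <- list()
  missing <- list()
  for (pid in names(esets)) {
    eset <- esets[[pid]]
    for (b in unique(eset$meta$block)) {
      idx <- which(eset$meta$block == b)
      sub <- subset_epochs(eset, idx)
      nkept <- sum(sub$meta$kept)
      if (nkept == 0) {
        missing[[length(missing) + 1]] <-
          data.frame(participant = pid, block = b,
                     brightness = sub$meta$brightness[1])
        next
      }
      p <- ssvep_power(sub, f0 = f0, db_first = db_first)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = pid, electrode = names(p),
        brightness = sub$meta$brightness[1],
        psd_db = as.numeric(p), n_epochs = nkept
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out[, c("participant", "electrode", "brightness")]))
    stop("duplicate (participant, electrode, brightness) keys")
  attr(out, "missing_blocks") <-
    if (length(missing)) dplyr::bind_rows(missing) else NULL
  out
}
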
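# Shared fixtures, built in code at test time.

# A small multi-channel recording containing given per-channel signals.
make_recording <- function(signals, srate = 256,
                           markers = data.frame(sample = 1, block = 1,
                                                brightness = 0)) {
  data <- do.call(rbind, signals)
  rownames(data) <- names(signals)
  eeg_recording(data, srate = srate, markers = markers)
}

# A recording with five contiguous stimulation blocks of pure tones.
make_block_recording <- function(amps, freq = 25, srate = 256,
                                 block_s = 20, channels = c("Oz", "Cz"),
                                 codes = -2:2) {
  bl <- block_s * srate
  n <- bl * length(amps)
  tvec <- (seq_len(n) - 1) / srate
  x <- numeric(n)
  for (b in seq_along(amps)) {
    idx <- ((b - 1) * bl + 1):(b * bl)
    x[idx] <- amps[b] * sin(2 * pi * freq * tvec[idx])
  }
  data <- matrix(rep(x, each = length(channels)), nrow = length(channels),
                 dimnames = list(channels, NULL))
  eeg_recording(data, srate,
                markers = data.frame(sample = (seq_along(amps) - 1) * bl + 1,
                                     block = seq_along(amps),
                                     brightness = codes,
                                     duration = block_s))
}

# An epoch set built directly (bypassing the continuous chain).
make_epochs <- function(n_epochs, channels, srate = 256, window = 2,
                        fill = function(e, nch, ns) {
                          matrix(stats::rnorm(nch * ns), nch, ns)
                        },
                        blocks = rep(1L, n_epochs),
                        brightness = rep(0, n_epochs)) {
  ns <- window * srate
  arr <- array(0, dim = c(n_epochs, length(channels), ns))
  for (e in seq_len(n_epochs)) arr[e, , ] <- fill(e, length(channels), ns)
  eeg_epochs(arr,
             data.frame(epoch = seq_len(n_epochs), block = blocks,
                        brightness = brightness, kept = TRUE),
             srate = srate, window = window, channel_labels = channels)
}

# Amplitude of a sinusoid at frequency f estimated by least squares.
tone_amplitude <- function(x, f, srate) {
  tvec <- (seq_along(x) - 1) / srate
  X <- cbind(sin(2 * pi * f * tvec), cos(2 * pi * f * tvec))
  cf <- stats::lm.fit(X, x)$coefficients
  sqrt(sum(cf^2))
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}
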
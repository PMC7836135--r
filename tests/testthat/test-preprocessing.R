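test_that("mastoid re-referencing equals the direct arithmetic", {
  set.seed(1)
  sig <- list(Oz = rnorm(100), Cz = rnorm(100), M1 = rnorm(100),
              M2 = rnorm(100))
  rec <- make_recording(sig)
  out <- rereference_mastoids(rec)
  ref <- (sig$M1 + sig$M2) / 2
  expect_equal(out$data["Oz", ], sig$Oz - ref)
  expect_equal(out$data["Cz", ], sig$Cz - ref)
  expect_false(any(c("M1", "M2") %in% rownames(out$data)))
  expect_identical(out$reference, "avg-mastoid")

  # zero mastoids leave the data unchanged
  sig0 <- sig; sig0$M1 <- sig0$M2 <- numeric(100)
  expect_equal(rereference_mastoids(make_recording(sig0))$data["Oz", ],
               sig0$Oz)
  # all channels equal to the mastoid mean -> all zero
  sigc <- list(Oz = ref, Cz = ref, M1 = sig$M1, M2 = sig$M2)
  expect_true(all(rereference_mastoids(make_recording(sigc))$data == 0))

  expect_error(rereference_mastoids(make_recording(sig[c("Oz", "M1")])),
               "M2")
})

test_that("the high-pass filter meets its frequency-response contract", {
  fs <- 500
  n <- fs * 30
  tvec <- (seq_len(n) - 1) / fs
  mk <- data.frame(sample = 1, block = 1, brightness = 0)
  run <- function(x) {
    highpass_fir(make_recording(list(ch = x), srate = fs,
                                markers = mk))$data[1, ]
  }
  mid <- (n %/% 4):(3 * n %/% 4)  # avoid edge transients when measuring

  # constant (DC) input is removed
  expect_lt(max(abs(run(rep(5, n))[mid])), 1e-6)
  # 25 Hz passband tone preserved within 1%
  y25 <- run(sin(2 * pi * 25 * tvec))
  expect_lt(abs(tone_amplitude(y25[mid], 25, fs) - 1), 0.01)
  # 0.2 Hz stopband tone attenuated by more than 20 dB
  y02 <- run(sin(2 * pi * 0.2 * tvec))
  expect_lt(tone_amplitude(y02[mid], 0.2, fs), 10^(-20 / 20))
  # half-amplitude (-6 dB) point sits at the 1 Hz cutoff (within 10%)
  y1 <- run(sin(2 * pi * 1 * tvec))
  a1 <- tone_amplitude(y1[mid], 1, fs)
  expect_gt(a1, 10^(-6.02 * 1.1 / 20))
  expect_lt(a1, 10^(-6.02 * 0.9 / 20))

  expect_error(highpass_fir(make_recording(list(ch = rnorm(50)), srate = fs,
                                           markers = mk)),
               "shorter than the filter")
})

test_that("Fourier downsampling preserves the stimulation band", {
  fs <- 500
  n <- fs * 20
  tvec <- (seq_len(n) - 1) / fs
  mk <- data.frame(sample = c(1, 5001), block = 1:2, brightness = c(0, 1))
  rec <- make_recording(list(ch = 3 * sin(2 * pi * 25 * tvec)), srate = fs,
                        markers = mk)
  out <- downsample(rec, 256)
  expect_equal(out$srate, 256)
  expect_equal(ncol(out$data), round(n * 256 / 500))
  expect_lt(abs(tone_amplitude(out$data[1, ], 25, 256) - 3), 0.03)
  # markers remapped to the nearest new sample
  expect_equal(out$markers$sample, c(1, round(5000 * 256 / 500) + 1))

  # identity when the target equals the original rate
  same <- downsample(rec, 500)
  expect_equal(same$data[1, ], rec$data[1, ], tolerance = 1e-6)

  # content above the new Nyquist guard band is removed
  rec120 <- make_recording(list(ch = sin(2 * pi * 120 * tvec)), srate = fs,
                           markers = mk)
  out120 <- downsample(rec120, 256)
  expect_lt(sqrt(mean(out120$data[1, ]^2)), 1e-6)

  expect_error(downsample(rec, 1000), "exceeds")
})

test_that("the line-noise notch removes 60 Hz and spares 25 Hz", {
  fs <- 256
  n <- fs * 20
  tvec <- (seq_len(n) - 1) / fs
  mk <- data.frame(sample = 1, block = 1, brightness = 0)
  run <- function(x) notch_line(make_recording(list(ch = x), srate = fs,
                                               markers = mk))$data[1, ]
  mid <- (n %/% 4):(3 * n %/% 4)
  expect_lt(tone_amplitude(run(sin(2 * pi * 60 * tvec))[mid], 60, fs),
            10^(-30 / 20))
  a25 <- tone_amplitude(run(sin(2 * pi * 25 * tvec))[mid], 25, fs)
  expect_lt(abs(20 * log10(a25)), 1)
  expect_true(all(run(numeric(n)) == 0))
  expect_error(notch_line(make_recording(list(ch = rnorm(n)), srate = 100,
                                         markers = mk)), "Nyquist")
})

test_that("epoching follows the sliding-window count formula", {
  rec <- make_block_recording(rep(1, 5))
  eset <- epoch_blocks(rec)
  expect_equal(nrow(eset$meta), 95)   # 5 blocks x 19 epochs
  expect_equal(as.integer(table(eset$meta$block)), rep(19L, 5))
  expect_equal(dim(eset$epochs)[3], 512)
  # brightness codes travel with the epochs
  expect_equal(unique(eset$meta$brightness[eset$meta$block == 1]), -2)

  # property: floor((d - window)/step) + 1 epochs for block durations 2..8 s
  for (d in 2:8) {
    r1 <- make_block_recording(1, block_s = d, codes = 0)
    expect_equal(nrow(epoch_blocks(r1)$meta), (d - 2) %/% 1 + 1,
                 info = paste("duration", d))
  }
  # block shorter than the window: zero epochs, with a warning
  short <- make_block_recording(c(1, 1), block_s = 20, codes = c(0, 1))
  short$markers$duration <- c(1, 20)
  expect_warning(es <- epoch_blocks(short), "shorter")
  expect_equal(nrow(es$meta), 19)
})

test_that("amplitude rejection matches a brute-force scan", {
  eset <- make_epochs(6, c("Oz", "Cz"),
                      fill = function(e, nch, ns) matrix(0, nch, ns))
  expect_true(all(reject_epochs(eset)$meta$kept))

  # one sample at 101 uV: that epoch (and only it) is rejected
  eset$epochs[3, 2, 77] <- 101
  out <- reject_epochs(eset)
  expect_identical(out$meta$kept, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  # a sample exactly at the threshold survives
  eset$epochs[3, 2, 77] <- 100
  expect_true(all(reject_epochs(eset)$meta$kept))

  set.seed(42)
  noisy <- make_epochs(30, c("Oz", "Cz", "Pz"),
                       fill = function(e, nch, ns)
                         matrix(rnorm(nch * ns, sd = 60), nch, ns),
                       blocks = rep(1:5, each = 6),
                       brightness = rep(-2:2, each = 6))
  out <- reject_epochs(noisy)
  oracle <- vapply(seq_len(30), function(e)
    all(abs(noisy$epochs[e, , ]) <= 100), logical(1))
  expect_identical(out$meta$kept, oracle)
  # conservation: kept + rejected = generated
  rej <- attr(out, "rejection_counts")
  expect_equal(sum(out$meta$kept) + sum(rej$n_rejected), 30)
})

test_that("a clean 25 Hz tone survives the voltage chain within 1 dB", {
  fs <- 500
  sp_amps <- rep(2, 5)
  rec <- make_block_recording(sp_amps, srate = fs, block_s = 20,
                              channels = c("Oz", "Cz", "M1", "M2"))
  rec$data[c("M1", "M2"), ] <- 0   # quiet mastoids: reference is a no-op
  pre <- preprocess_recording(rec, target_rate = 256)
  eset <- reject_epochs(epoch_blocks(pre))
  p_chain <- ssvep_power(subset_epochs(eset, which(eset$meta$block == 3)))

  ref <- make_block_recording(sp_amps, srate = 256, block_s = 20,
                              channels = c("Oz", "Cz"))
  eref <- epoch_blocks(ref)
  p_ref <- ssvep_power(subset_epochs(eref, which(eref$meta$block == 3)))
  expect_lt(abs(p_chain[["Oz"]] - p_ref[["Oz"]]), 1)
})
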
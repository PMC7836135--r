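#' Cohort parameters for the synthetic participant table
#'
#' Defines the joint distribution of the three participant-level moderators:
#' menstrual pain (VAS 0-100), somatic symptom sum, and bladder pain
#' (VAS 0-100). Covariates are generated from a latent correlated Gaussian
#' (Gaussian copula) mapped affinely to the requested means/SDs and clipped
#' at the scale bounds. Defaults reproduce the moments and pairwise
#' correlations of a dysmenorrhea-enriched cohort of reproductive-age women
#' (menstrual pain M=62.5, SD=26.1; somatic symptoms M=2.37, SD=2.4; bladder
#' pain at first urge M=12.2, SD=16; r(menstrual, bladder)=0.28,
#' r(bladder, somatic)=0.28, r(somatic, menstrual)=0.16).
#'
#' Clipping at the bounds slightly biases the realized moments and
#' attenuates the correlations (bladder pain is strongly left-censored at 0,
#' as in real cohorts where many participants report no bladder pain); the
#' bias is documented in the methods vignette and covered by tolerance
#' tests.
#'
#' @param n_participants Number of participants.
#' @param covariate_means,covariate_sds Named numeric vectors for
#'   `menstrual_pain`, `somatic_symptoms`, `bladder_pain`.
#' @param covariate_corrs 3x3 correlation matrix (order: menstrual, somatic,
#'   bladder). Must be symmetric positive-definite with unit diagonal.
#' @param bounds Named list of length-2 numeric bounds per covariate. The
#'   somatic-sum upper bound is exposed because instrument versions differ
#'   in item count.
#' @param seed Integer seed; all generator functions are deterministic given
#'   their seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 147,
                          covariate_means = c(menstrual_pain = 62.5,
                                              somatic_symptoms = 2.37,
                                              bladder_pain = 12.2),
                          covariate_sds = c(menstrual_pain = 26.1,
                                            somatic_symptoms = 2.4,
                                            bladder_pain = 16),
                          covariate_corrs = default_covariate_corrs(),
                          bounds = list(menstrual_pain = c(0, 100),
                                        somatic_symptoms = c(0, 59),
                                        bladder_pain = c(0, 100)),
                          seed = 1L) {
  vars <- c("menstrual_pain", "somatic_symptoms", "bladder_pain")
  stopifnot(n_participants >= 1,
            identical(names(covariate_means), vars),
            identical(names(covariate_sds), vars),
            all(covariate_sds >= 0),
            identical(names(bounds), vars))
  R <- as.matrix(covariate_corrs)
  if (!isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(diag(R), rep(1, 3),
                                                       check.attributes = FALSE)))
    stop("covariate_corrs must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "covariate_corrs is not positive-definite (min eigenvalue %.3g)",
      min(ev)))
  structure(
    list(n_participants = as.integer(n_participants),
         covariate_means = covariate_means, covariate_sds = covariate_sds,
         covariate_corrs = R, bounds = bounds, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' @rdname cohort_params
#' @export
default_covariate_corrs <- function() {
  R <- matrix(c(1, 0.16, 0.28,
                0.16, 1, 0.28,
                0.28, 0.28, 1), 3, 3)
  dimnames(R) <- rep(list(c("menstrual_pain", "somatic_symptoms",
                            "bladder_pain")), 2)
  R
}

#' Generate a synthetic participant covariate table
#'
#' Draws the three moderators from the Gaussian copula described in
#' [cohort_params()]. Sample moments converge to the requested values as n
#' grows, up to the documented clipping bias at the scale bounds.
#'
#' @param params A `cohort_params` object.
#' @return A tibble with columns `participant`, `menstrual_pain`,
#'   `somatic_symptoms`, `bladder_pain`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_participants = 20, seed = 7))
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  vars <- names(params$covariate_means)
  Z <- withr::with_seed(params$seed,
    MASS::mvrnorm(params$n_participants, mu = rep(0, 3),
                  Sigma = params$covariate_corrs))
  Z <- matrix(Z, ncol = 3)
  out <- tibble::tibble(
    participant = sprintf("p%03d", seq_len(params$n_participants))
  )
  for (k in seq_along(vars)) {
    v <- params$covariate_means[k] + params$covariate_sds[k] * Z[, k]
    b <- params$bounds[[vars[k]]]
    out[[vars[k]]] <- pmin(pmax(v, b[1]), b[2])
  }
  out
}

#' Expected covariate means after clipping at the scale bounds
#'
#' Clipping the latent Gaussian covariates at their scale bounds shifts
#' their means (most visibly for bladder pain, which is strongly
#' left-censored at 0). This closed-form clipped-normal mean,
#' \eqn{a\Phi(\alpha) + b(1-\Phi(\beta)) + \mu(\Phi(\beta)-\Phi(\alpha)) +
#' \sigma(\phi(\alpha)-\phi(\beta))}, is the mean of the population the
#' generator actually produces, and is therefore the point at which the
#' planted level-2 model centers its moderators.
#'
#' @param params A [cohort_params()].
#' @return Named numeric vector of expected realized means.
#' @export
censored_covariate_means <- function(params = cohort_params()) {
  vars <- names(params$covariate_means)
  out <- vapply(vars, function(v) {
    mu <- params$covariate_means[[v]]
    sg <- params$covariate_sds[[v]]
    b <- params$bounds[[v]]
    if (sg == 0) return(min(max(mu, b[1]), b[2]))
    al <- (b[1] - mu) / sg
    be <- (b[2] - mu) / sg
    b[1] * stats::pnorm(al) + b[2] * stats::pnorm(be, lower.tail = FALSE) +
      mu * (stats::pnorm(be) - stats::pnorm(al)) +
      sg * (stats::dnorm(al) - stats::dnorm(be))
  }, numeric(1))
  stats::setNames(out, vars)
}

#' Plantable effect parameters for the synthetic study
#'
#' Holds every parameter the generator plants so that downstream recovery is
#' testable: the level-2 coefficients of the two-stage moderation model
#' (rows: rating intercept b0, brightness slope b1, PSD slope b2; columns:
#' intercept, menstrual pain, somatic symptoms, bladder pain; units are
#' Gracely Box Scale points per moderator unit), the level-1 residual SD,
#' SDs of participant random effects, and the SSVEP power model at the
#' occipital driver electrode (dB intercept and dB-per-brightness-step
#' slope, between-participant SDs, and level-1 dB noise).
#'
#' Defaults plant the published-scale effect sizes this paradigm produces
#' (e.g. mean unpleasantness 8.0 GBS, +0.36 GBS per brightness step,
#' +0.11 GBS per dB, bladder-pain moderation 0.06 GBS/VAS on the intercept
#' and 0.01 on the PSD slope; SSVEP -23.76 dB intercept, +2.05 dB/step).
#' The variance defaults were derived by partitioning the level-2 mean
#' squares typical of this paradigm into a level-1 sampling part and a
#' between-participant part; the methods vignette details the derivation.
#' With all moderator coefficients 0 the generator produces a null
#' moderation dataset.
#'
#' @param gamma 3x4 numeric matrix of level-2 coefficients (see above).
#' @param level1_residual_sd Rating residual SD, GBS units.
#' @param random_effect_sds Named SDs of participant deviations of b0, b1,
#'   b2 (independent by default).
#' @param ssvep_base_db,ssvep_slope_db Mean 25 Hz power intercept and slope
#'   (dB, dB/step) at the driver electrode.
#' @param ssvep_base_subject_sd,ssvep_slope_subject_sd Between-participant
#'   SDs of the SSVEP dB intercept and slope.
#' @param psd_noise_sd Level-1 (block-to-block) dB noise of the PSD
#'   estimates in the statistical fast path ([simulate_psd_table()]).
#' @param topography_decay Spatial falloff (per radian of angular distance
#'   from the driver electrode) of the planted SSVEP amplitude.
#' @param moderator_center Population means at which the generator centers
#'   the moderators when applying `gamma`; defaults to the realized
#'   (post-clipping) means of the default cohort
#'   ([censored_covariate_means()]), so that the analysis' grand-mean
#'   centering and the generator's centering coincide in expectation.
#' @return A list of class `planted_model`.
#' @export
planted_model <- function(gamma = default_gamma(),
                          level1_residual_sd = 1.0,
                          random_effect_sds = c(b0 = 3.84, b1 = 0.75,
                                                b2 = 0.39),
                          ssvep_base_db = -23.76,
                          ssvep_slope_db = 2.05,
                          ssvep_base_subject_sd = 5.58,
                          ssvep_slope_subject_sd = 0.91,
                          psd_noise_sd = 2.0,
                          topography_decay = 1.2,
                          moderator_center = censored_covariate_means()) {
  gamma <- as.matrix(gamma)
  stopifnot(identical(dim(gamma), c(3L, 4L)),
            level1_residual_sd >= 0, all(random_effect_sds >= 0),
            ssvep_base_subject_sd >= 0, ssvep_slope_subject_sd >= 0,
            psd_noise_sd >= 0, topography_decay >= 0)
  dimnames(gamma) <- list(c("b0", "b1", "b2"),
                          c("intercept", "menstrual_pain",
                            "somatic_symptoms", "bladder_pain"))
  structure(
    list(gamma = gamma, level1_residual_sd = level1_residual_sd,
         random_effect_sds = random_effect_sds,
         ssvep_base_db = ssvep_base_db, ssvep_slope_db = ssvep_slope_db,
         ssvep_base_subject_sd = ssvep_base_subject_sd,
         ssvep_slope_subject_sd = ssvep_slope_subject_sd,
         psd_noise_sd = psd_noise_sd,
         topography_decay = topography_decay,
         moderator_center = moderator_center),
    class = "planted_model"
  )
}

#' @rdname planted_model
#' @export
default_gamma <- function() {
  matrix(c(8.00, 0.01, -0.14, 0.06,
           0.36, 0.01, -0.03, -0.003,
           0.11, -0.001, -0.005, 0.01),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("b0", "b1", "b2"),
                         c("intercept", "menstrual_pain",
                           "somatic_symptoms", "bladder_pain")))
}

#' @rdname planted_model
#' @param ... Passed to [planted_model()].
#' @export
null_planted_model <- function(...) {
  g <- default_gamma()
  g[, c("menstrual_pain", "somatic_symptoms", "bladder_pain")] <- 0
  planted_model(gamma = g, ...)
}

#' Session layout of the visual stimulation task
#'
#' Describes one EEG session: five 20-second blocks of 25 Hz pattern-reversal
#' stimulation, one per brightness intensity (1, 30, 60, 90, 120 lux, coded
#' mean-centered -2..2), recorded at 500 Hz from the 32-channel montage plus
#' two mastoids. Noise parameters control the artifact content: pink (1/f)
#' background noise, optional 60 Hz line contamination and blink transients.
#' The default `pink_rms = NULL` scales the background noise to 1.5x the
#' planted tone amplitude: broadband noise then dominates the raw trace,
#' while the stimulation-frequency bin keeps the strongly positive
#' signal-to-noise ratio this paradigm exhibits (the noise floor sits about
#' 7 dB below the dimmest block, so the planted dB line stays realizable;
#' see the methods vignette). The artifact-light default
#' (`line_amplitude = 0`, `blink_rate = 0`) emulates data after
#' component-based cleaning.
#'
#' @param sampling_rate Acquisition rate, Hz.
#' @param block_duration Stimulation block length, seconds.
#' @param n_blocks Number of blocks; must equal the number of brightness
#'   levels.
#' @param stim_freq Stimulation (pattern-reversal) frequency, Hz. Must lie
#'   below the Nyquist frequency of `target_rate`, the rate the analysis
#'   chain resamples to.
#' @param brightness_codes Mean-centered brightness codes, ordered.
#' @param lux Physical intensities corresponding to the codes.
#' @param lead_in,inter_block_gap,tail Unstimulated padding (s) before the
#'   first block, between blocks, and after the last block.
#' @param target_rate Analysis sampling rate used for the Nyquist check.
#' @param pink_rms Pink-noise RMS amplitude in microvolts, or `NULL` for the
#'   SNR-matched default.
#' @param line_amplitude 60 Hz line-noise amplitude, microvolts.
#' @param blink_rate Mean blink rate, events per second.
#' @param blink_amplitude Blink transient peak amplitude at the brow,
#'   microvolts.
#' @param randomize_blocks Randomize block order across participants, as in
#'   the task.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(sampling_rate = 500, block_duration = 20,
                         n_blocks = 5, stim_freq = 25,
                         brightness_codes = -2:2,
                         lux = c(1, 30, 60, 90, 120),
                         lead_in = 2, inter_block_gap = 2, tail = 1,
                         target_rate = 256,
                         pink_rms = NULL, line_amplitude = 0,
                         blink_rate = 0, blink_amplitude = 150,
                         randomize_blocks = TRUE) {
  if (n_blocks != length(brightness_codes))
    stop("n_blocks must equal the number of brightness levels")
  if (stim_freq >= target_rate / 2)
    stop(sprintf("stim_freq (%g Hz) must be below the post-downsampling Nyquist (%g Hz)",
                 stim_freq, target_rate / 2))
  if (stim_freq >= sampling_rate / 2)
    stop("stim_freq must be below the acquisition Nyquist")
  stopifnot(block_duration > 0, length(lux) == n_blocks,
            lead_in >= 0, inter_block_gap >= 0, tail >= 0)
  structure(
    list(sampling_rate = sampling_rate, block_duration = block_duration,
         n_blocks = as.integer(n_blocks), stim_freq = stim_freq,
         brightness_codes = brightness_codes, lux = lux,
         lead_in = lead_in, inter_block_gap = inter_block_gap, tail = tail,
         target_rate = target_rate,
         pink_rms = pink_rms, line_amplitude = line_amplitude,
         blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         randomize_blocks = randomize_blocks),
    class = "session_spec"
  )
}

# Cache for pipeline gain calibrations (keyed by parameter string).
.calib_cache <- new.env(parent = emptyenv())

#' Pipeline gain calibration for the planted SSVEP
#'
#' The SSVEP is planted on the dB scale: the generator promises that a
#' noise-free session, pushed through the full analysis chain
#' (re-reference, high-pass, resampling, notch, epoching, surface
#' Laplacian, Hamming-taper PSD), yields the requested dB power at the
#' driver electrode. Because every stage is linear and deterministic, it
#' suffices to measure once, for a unit-amplitude tone with the planted
#' topography, the dB power the chain reports; amplitudes for any target
#' dB then follow from `A = 10^((target - gain)/20)`.
#'
#' @param spec A [session_spec()].
#' @param planted A [planted_model()] (supplies the topography decay).
#' @param montage Scalp montage.
#' @param driver Driver electrode label (default the montage a-priori
#'   channel).
#' @return dB power at the driver electrode for a unit-amplitude (1 uV at
#'   the driver) planted tone.
#' @export
pipeline_gain_db <- function(spec = session_spec(), planted = planted_model(),
                             montage = montage_1020(), driver = NULL) {
  driver <- driver %||% montage$a_priori
  key <- paste(spec$sampling_rate, spec$block_duration, spec$n_blocks,
               spec$stim_freq, spec$lead_in, spec$inter_block_gap, spec$tail,
               spec$target_rate, planted$topography_decay, driver,
               paste(montage$labels, collapse = ","), sep = "|")
  hit <- get0(key, envir = .calib_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  rec <- synth_session_core(
    amp_per_block = rep(1, spec$n_blocks),
    codes = spec$brightness_codes, spec = spec, planted = planted,
    montage = montage, driver = driver, seed = 1L, noise = FALSE
  )
  eset <- epoch_blocks(preprocess_recording(rec, target_rate = spec$target_rate))
  eset <- reject_epochs(eset)
  kernel <- build_csd_kernel(montage)
  eset <- apply_laplacian(eset, kernel)
  per_block <- vapply(split(seq_len(nrow(eset$meta)), eset$meta$block),
                      function(idx) {
                        sub <- subset_epochs(eset, idx)
                        unname(ssvep_power(sub, f0 = spec$stim_freq)[driver])
                      }, numeric(1))
  gain <- mean(per_block)
  assign(key, gain, envir = .calib_cache)
  gain
}

# Expected post-pipeline linear power at the stimulation bin of the driver
# electrode for unit-RMS pink noise alone, estimated once per session
# layout by pushing a noise-only session through the full chain and
# averaging the bin power over all epochs. Blink and line components are
# spectrally remote from the stimulation bin and ignored.
noise_floor_unit <- function(spec, montage, driver) {
  key <- paste("floor", spec$sampling_rate, spec$block_duration,
               spec$n_blocks, spec$stim_freq, spec$lead_in,
               spec$inter_block_gap, spec$tail, spec$target_rate, driver,
               paste(montage$labels, collapse = ","), sep = "|")
  hit <- get0(key, envir = .calib_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  nspec <- spec
  nspec$pink_rms <- 1
  nspec$line_amplitude <- 0
  nspec$blink_rate <- 0
  kernel <- build_csd_kernel(montage)
  # average over several noise realizations: each session contributes ~95
  # roughly-exponential per-epoch bin powers, so four sessions pin the
  # floor to a few percent
  floors <- vapply(1:4, function(s) {
    rec <- synth_session_core(
      amp_per_block = rep(0, spec$n_blocks), codes = spec$brightness_codes,
      spec = nspec, planted = planted_model(), montage = montage,
      driver = driver, seed = 424242L + s, noise = TRUE
    )
    eset <- epoch_blocks(preprocess_recording(rec,
                                              target_rate = spec$target_rate))
    eset <- apply_laplacian(eset, kernel)
    db <- ssvep_power(eset, f0 = spec$stim_freq)[driver]
    10^(unname(db) / 10)
  }, numeric(1))
  floor_lin <- mean(floors)
  assign(key, floor_lin, envir = .calib_cache)
  floor_lin
}

# Construct the deterministic (and optionally noisy) session signal.
# amp_per_block: tone amplitude at the driver electrode, per block, uV.
synth_session_core <- function(amp_per_block, codes, spec, planted, montage,
                               driver, seed, noise = TRUE) {
  fs <- spec$sampling_rate
  nb <- spec$n_blocks
  bl <- round(spec$block_duration * fs)
  gap <- round(spec$inter_block_gap * fs)
  lead <- round(spec$lead_in * fs)
  n <- lead + nb * bl + (nb - 1) * gap + round(spec$tail * fs)

  scalp_pos <- montage$pos
  mast_pos <- mastoid_positions()
  pos <- rbind(scalp_pos, mast_pos)
  labels <- rownames(pos)
  w <- exp(-planted$topography_decay *
             angular_distance(pos, scalp_pos[driver, ]))

  onsets <- lead + (seq_len(nb) - 1) * (bl + gap) + 1
  data <- matrix(0, nrow = length(labels), ncol = n,
                 dimnames = list(labels, NULL))
  tvec <- (seq_len(n) - 1) / fs
  for (b in seq_len(nb)) {
    idx <- onsets[b]:(onsets[b] + bl - 1)
    tone <- amp_per_block[b] * sin(2 * pi * spec$stim_freq * tvec[idx])
    data[, idx] <- data[, idx] + outer(w, tone)
  }

  if (noise) {
    data <- data + withr::with_seed(seed, {
      nz <- matrix(0, nrow = length(labels), ncol = n)
      pink_rms <- spec$pink_rms %||% (5 * mean(amp_per_block))
      if (pink_rms > 0)
        for (ch in seq_along(labels))
          nz[ch, ] <- pink_noise(n, fs, rms = pink_rms)
      if (spec$line_amplitude > 0) {
        ph <- stats::runif(length(labels), 0, 2 * pi)
        nz <- nz + spec$line_amplitude *
          sin(outer(ph, rep(1, n)) + 2 * pi * 60 * outer(rep(1, length(labels)), tvec))
      }
      if (spec$blink_rate > 0) {
        brow <- (scalp_pos["Fp1", ] + scalp_pos["Fp2", ]) / 2
        brow <- brow / sqrt(sum(brow^2))
        wb <- exp(-3 * angular_distance(pos, brow))
        n_ev <- stats::rpois(1, spec$blink_rate * n / fs)
        if (n_ev > 0) {
          centers <- sort(stats::runif(n_ev, 0.2, n / fs - 0.2))
          half <- round(0.15 * fs)
          for (ct in centers) {
            cs <- round(ct * fs)
            idx <- max(1, cs - half):min(n, cs + half)
            bump <- spec$blink_amplitude *
              0.5 * (1 + cos(pi * (idx - cs) / half))
            nz[, idx] <- nz[, idx] + outer(wb, bump)
          }
        }
      }
      nz
    })
  }

  eeg_recording(
    data = data, srate = fs,
    markers = data.frame(sample = onsets, block = seq_len(nb),
                         brightness = codes,
                         duration = spec$block_duration),
    reference = "common",
    log = sprintf("synthesized session (%d ch, %.1f s)", length(labels), n / fs)
  )
}

# 1/f (pink) noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, fs, rms = 1, f_floor = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)             # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, f_floor))
  shape[1] <- 0                    # no DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Generate one synthetic EEG session
#'
#' Produces a continuous 34-channel recording (32 scalp + 2 mastoids) with
#' block onset markers and an embedded 25 Hz SSVEP whose post-pipeline dB
#' power at the driver electrode follows
#' `ssvep_base_db + ssvep_slope_db * brightness + participant deviation`.
#' The conversion from target dB to sinusoid amplitude uses the measured
#' pipeline gain ([pipeline_gain_db()]); additive pink noise, line noise and
#' blink transients follow the session spec.
#'
#' @param participant_row One-row data frame identifying the participant
#'   (used only for seeding/identification), or `NULL`.
#' @param planted A [planted_model()].
#' @param spec A [session_spec()].
#' @param seed Integer seed for this session's randomness (subject
#'   deviations, noise, block order).
#' @param subject_deviation Optional named numeric `c(base =, slope =)`
#'   overriding the drawn participant deviations (dB, dB/step).
#' @param montage Scalp montage.
#' @return An `eeg_recording`.
#' @export
generate_session_eeg <- function(participant_row = NULL,
                                 planted = planted_model(),
                                 spec = session_spec(), seed = 1L,
                                 subject_deviation = NULL,
                                 montage = montage_1020()) {
  stopifnot(inherits(planted, "planted_model"), inherits(spec, "session_spec"))
  driver <- montage$a_priori
  gain <- pipeline_gain_db(spec, planted, montage, driver)

  drawn <- withr::with_seed(seed, list(
    dev = c(base = stats::rnorm(1, 0, planted$ssvep_base_subject_sd),
            slope = stats::rnorm(1, 0, planted$ssvep_slope_subject_sd)),
    order = if (spec$randomize_blocks) sample(spec$n_blocks) else
      seq_len(spec$n_blocks)
  ))
  dev <- subject_deviation %||% drawn$dev
  codes <- spec$brightness_codes[drawn$order]
  target_db <- (planted$ssvep_base_db + dev[["base"]]) +
    (planted$ssvep_slope_db + dev[["slope"]]) * codes
  amp <- 10^((target_db - gain) / 20)

  # Background noise also contributes power at the stimulation bin, so the
  # planted amplitude is reduced until expected total bin power (signal +
  # measured noise floor) hits the target. Targets below the noise floor
  # are clamped to zero signal - the floor is a physical lower bound.
  rms <- spec$pink_rms %||% (1.5 * mean(amp))
  spec$pink_rms <- rms
  if (rms > 0) {
    floor_lin <- rms^2 * noise_floor_unit(spec, montage, driver)
    p_unit <- 10^(gain / 10)
    p_sig <- pmax(10^(target_db / 10) - floor_lin, 0)
    amp <- sqrt(p_sig / p_unit)
  }

  rec <- synth_session_core(amp_per_block = amp, codes = codes, spec = spec,
                            planted = planted, montage = montage,
                            driver = driver, seed = seed + 1L, noise = TRUE)
  if (!is.null(participant_row) && "participant" %in% names(participant_row))
    rec$participant <- participant_row$participant
  rec
}

#' Generate per-block unpleasantness ratings from the planted model
#'
#' Draws the participant's level-1 coefficients (rating intercept,
#' brightness slope, PSD slope) from the planted level-2 model plus
#' independent Gaussian random effects, then produces one Gracely Box Scale
#' rating per block as the level-1 linear predictor plus residual noise.
#' The PSD predictor is centered within participant, matching the analysis
#' model, so the planted intercept is the mean rating. Ratings are clipped
#' to the 0-20 scale by default; rounding to scale integers is optional
#' (the analysis treats ratings as continuous).
#'
#' @param participant_row One-row data frame with `menstrual_pain`,
#'   `somatic_symptoms`, `bladder_pain`.
#' @param psd_by_block Data frame with columns `brightness` and `psd_db`:
#'   the five PSD estimates at the driver electrode.
#' @param planted A [planted_model()].
#' @param seed Integer seed.
#' @param clip Clip ratings to `[0, 20]`.
#' @param round_to_integer Round ratings to scale integers.
#' @return A tibble with columns `brightness`, `rating`, and the drawn
#'   coefficients as attributes `b0`, `b1`, `b2`.
#' @export
generate_ratings <- function(participant_row, psd_by_block,
                             planted = planted_model(), seed = 1L,
                             clip = TRUE, round_to_integer = FALSE) {
  stopifnot(inherits(planted, "planted_model"))
  need <- names(planted$moderator_center)
  if (!all(need %in% names(participant_row)))
    stop("participant_row must contain ", paste(need, collapse = ", "))
  codes <- sort(unique(psd_by_block$brightness))
  expected <- -2:2
  missing <- setdiff(expected, codes)
  if (length(missing) > 0)
    stop("missing PSD for brightness block(s): ",
         paste(missing, collapse = ", "))
  psd_by_block <- psd_by_block[order(psd_by_block$brightness), ]
  if (any(!is.finite(psd_by_block$psd_db)))
    stop("missing PSD for brightness block(s): ",
         paste(psd_by_block$brightness[!is.finite(psd_by_block$psd_db)],
               collapse = ", "))

  x <- c(1, as.numeric(participant_row[1, need]) - planted$moderator_center)
  mu <- drop(planted$gamma %*% x)
  draws <- withr::with_seed(seed, list(
    re = stats::rnorm(3, 0, planted$random_effect_sds),
    eps = stats::rnorm(length(expected), 0, planted$level1_residual_sd)
  ))
  b <- unname(mu + draws$re)
  psd_c <- psd_by_block$psd_db - mean(psd_by_block$psd_db)
  rating <- b[1] + b[2] * psd_by_block$brightness + b[3] * psd_c + draws$eps
  if (clip) rating <- pmin(pmax(rating, 0), 20)
  if (round_to_integer) rating <- round(rating)
  out <- tibble::tibble(brightness = psd_by_block$brightness, rating = rating)
  attr(out, "b0") <- b[1]; attr(out, "b1") <- b[2]; attr(out, "b2") <- b[3]
  out
}

#' Fast statistical simulation of the PSD table
#'
#' Draws per-block 25 Hz dB power at the driver electrode directly from the
#' planted statistical model (subject deviations plus level-1 dB noise),
#' bypassing EEG synthesis. This is the path used for Monte Carlo studies
#' of the two-stage estimator, where thousands of sessions are needed; the
#' EEG path ([generate_session_eeg()]) verifies that the full signal chain
#' realizes the same dB model.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param planted A [planted_model()].
#' @param seed Integer seed.
#' @param electrode Electrode label for the emitted rows.
#' @param brightness_codes Centered brightness codes.
#' @return A PSD table: tibble (participant, electrode, brightness,
#'   psd_db, n_epochs).
#' @export
simulate_psd_table <- function(cohort, planted = planted_model(), seed = 1L,
                               electrode = "Oz", brightness_codes = -2:2) {
  n <- nrow(cohort)
  nb <- length(brightness_codes)
  draws <- withr::with_seed(seed, list(
    base = stats::rnorm(n, 0, planted$ssvep_base_subject_sd),
    slope = stats::rnorm(n, 0, planted$ssvep_slope_subject_sd),
    eps = matrix(stats::rnorm(n * nb, 0, planted$psd_noise_sd), n, nb)
  ))
  psd <- outer(planted$ssvep_base_db + draws$base, rep(1, nb)) +
    outer(planted$ssvep_slope_db + draws$slope, brightness_codes) +
    draws$eps
  tibble::tibble(
    participant = rep(cohort$participant, each = nb),
    electrode = electrode,
    brightness = rep(brightness_codes, n),
    psd_db = as.numeric(t(psd)),
    n_epochs = 19L
  )
}

#' Simulate a full study (statistical fast path)
#'
#' Cohort covariates, driver-electrode PSD table, and ratings for every
#' participant, all from the planted model. Used by the Monte Carlo
#' recovery and calibration harnesses.
#'
#' @param params A [cohort_params()]; its `seed` is ignored in favour of
#'   `seed`.
#' @param planted A [planted_model()].
#' @param seed Integer seed for the whole study.
#' @param clip,round_to_integer Passed to [generate_ratings()].
#' @return List with `covariates`, `psd` and `ratings` tibbles.
#' @export
simulate_study <- function(params = cohort_params(),
                           planted = planted_model(), seed = 1L,
                           clip = TRUE, round_to_integer = FALSE) {
  params$seed <- seed
  cohort <- generate_cohort(params)
  psd <- simulate_psd_table(cohort, planted, seed = seed + 1L)
  ratings <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    r <- generate_ratings(cohort[i, ], psd[psd$participant ==
                                            cohort$participant[i], ],
                          planted, seed = seed + 1L + i,
                          clip = clip, round_to_integer = round_to_integer)
    r$participant <- cohort$participant[i]
    r
  }))
  list(covariates = cohort, psd = psd,
       ratings = ratings[, c("participant", "brightness", "rating")])
}

#' Monte Carlo replication of the two-stage moderation analysis
#'
#' Repeatedly simulates studies under the planted model and refits the
#' second-level moderation models at the driver electrode, returning the
#' per-replicate estimates and p-values for every (model, term) cell. Used
#' for parameter-recovery and type-I-error calibration.
#'
#' @param n_reps Number of replicate cohorts.
#' @param params A [cohort_params()].
#' @param planted A [planted_model()].
#' @param seed Integer seed; replicate r uses `seed + r * 1000`.
#' @param clip,round_to_integer Passed to [generate_ratings()]. Defaults
#'   disable clipping: recovery properties concern the uncensored model
#'   (see the methods vignette).
#' @return Tibble with columns `rep`, `model`, `term`, `b`, `se`, `p`.
#' @export
replicate_recovery <- function(n_reps = 200, params = cohort_params(),
                               planted = planted_model(), seed = 1L,
                               clip = FALSE, round_to_integer = FALSE) {
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    study <- simulate_study(params, planted, seed = seed + r * 1000L,
                            clip = clip, round_to_integer = round_to_integer)
    fit <- analyze_moderation(study$psd, study$ratings, study$covariates,
                              a_priori = "Oz")
    l2 <- fit$level2[, c("model", "term", "b", "se", "p")]
    l2$rep <- r
    res[[r]] <- l2
  }
  dplyr::bind_rows(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
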
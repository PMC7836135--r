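test_that("cohort generator reproduces the planted correlation structure", {
  cohort <- generate_cohort(cohort_params(n_participants = 10000, seed = 11))
  expect_equal(nrow(cohort), 10000)
  # clipping at the scale bounds attenuates the latent correlation a little;
  # the realized value must stay close to the planted 0.28
  expect_lt(abs(cor(cohort$menstrual_pain, cohort$bladder_pain) - 0.28), 0.03)
  expect_lt(abs(cor(cohort$bladder_pain, cohort$somatic_symptoms) - 0.28), 0.05)
  expect_lt(abs(cor(cohort$somatic_symptoms, cohort$menstrual_pain) - 0.16), 0.03)
  # moments: converge to the planted values up to the documented clipping bias
  expect_lt(abs(mean(cohort$menstrual_pain) - 62.5), 1.5)
  expect_lt(abs(sd(cohort$menstrual_pain) - 26.1), 2.5)
  expect_lt(abs(mean(cohort$bladder_pain) - 12.2), 2.5)
  expect_lt(abs(mean(cohort$somatic_symptoms) - 2.37), 0.4)
  expect_true(all(cohort$menstrual_pain >= 0 & cohort$menstrual_pain <= 100))
  expect_true(all(cohort$bladder_pain >= 0 & cohort$bladder_pain <= 100))
})

test_that("degenerate cohorts and the seed contract behave as specified", {
  # zero SDs, zero correlations: every participant sits at the mean
  p0 <- cohort_params(n_participants = 5,
                      covariate_sds = c(menstrual_pain = 0,
                                        somatic_symptoms = 0,
                                        bladder_pain = 0),
                      covariate_corrs = diag(3), seed = 1)
  c0 <- generate_cohort(p0)
  expect_true(all(c0$menstrual_pain == 62.5))
  expect_true(all(c0$somatic_symptoms == 2.37))
  expect_true(all(c0$bladder_pain == 12.2))

  a <- generate_cohort(cohort_params(n_participants = 147, seed = 1))
  b <- generate_cohort(cohort_params(n_participants = 147, seed = 2))
  expect_identical(names(a), names(b))
  expect_false(isTRUE(all.equal(a$menstrual_pain, b$menstrual_pain)))
  expect_identical(a, generate_cohort(cohort_params(n_participants = 147,
                                                    seed = 1)))
})

test_that("a non-positive-definite correlation matrix is rejected", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_params(covariate_corrs = R), "positive-definite")
  expect_error(cohort_params(covariate_corrs = diag(3) * 2), "unit diagonal")
})

test_that("session spec validates the stimulation frequency and block count", {
  expect_error(session_spec(stim_freq = 130), "Nyquist")
  expect_error(session_spec(n_blocks = 4), "brightness levels")
  expect_silent(session_spec())
})

test_that("noise-free, slope-free sessions contain a pure repeating tone", {
  pm <- planted_model(ssvep_slope_db = 0, ssvep_base_subject_sd = 0,
                      ssvep_slope_subject_sd = 0)
  sp <- session_spec(pink_rms = 0, randomize_blocks = FALSE)
  rec <- generate_session_eeg(NULL, pm, sp, seed = 3)
  fs <- rec$srate
  bl <- sp$block_duration * fs
  seg <- lapply(rec$markers$sample, function(s) rec$data["Oz", s:(s + bl - 1)])
  # identical in every block
  for (b in 2:5) expect_equal(seg[[b]], seg[[1]], tolerance = 1e-12)
  # pure 25 Hz: residual after projecting onto the 25 Hz quadrature pair
  tvec <- (seq_len(bl) - 1) / fs
  X <- cbind(sin(2 * pi * 25 * tvec), cos(2 * pi * 25 * tvec))
  expect_lt(max(abs(lm.fit(X, seg[[1]])$residuals)), 1e-10)
  # deterministic for a fixed seed
  rec2 <- generate_session_eeg(NULL, pm, sp, seed = 3)
  expect_identical(rec$data, rec2$data)
})

test_that("high-amplitude blinks produce epochs that the threshold rejects", {
  pm <- planted_model(ssvep_base_subject_sd = 0, ssvep_slope_subject_sd = 0)
  sp <- session_spec(pink_rms = 0.01, blink_rate = 0.4,
                     blink_amplitude = 400, randomize_blocks = FALSE)
  rec <- generate_session_eeg(NULL, pm, sp, seed = 9)
  eset <- reject_epochs(epoch_blocks(preprocess_recording(rec)), 100)
  expect_gt(sum(!eset$meta$kept), 0)
  # rejection equals a brute-force scan of every epoch
  peaks <- apply(abs(eset$epochs), 1, max)
  expect_identical(eset$meta$kept, peaks <= 100)
})

test_that("ratings follow the planted level-2 model in degenerate cases", {
  psd <- data.frame(brightness = -2:2, psd_db = c(-28, -26, -24, -22, -20))
  row <- data.frame(menstrual_pain = 62.5, somatic_symptoms = 2.37,
                    bladder_pain = 12.2)
  pm0 <- planted_model(gamma = matrix(0, 3, 4), level1_residual_sd = 0,
                       random_effect_sds = c(b0 = 0, b1 = 0, b2 = 0))
  expect_true(all(generate_ratings(row, psd, pm0, seed = 1)$rating == 0))

  g <- matrix(0, 3, 4); g[1, 1] <- 8
  pm8 <- planted_model(gamma = g, level1_residual_sd = 0,
                       random_effect_sds = c(b0 = 0, b1 = 0, b2 = 0))
  expect_true(all(generate_ratings(row, psd, pm8, seed = 1)$rating == 8))

  # clipping keeps ratings on the 0-20 scale
  g[1, 1] <- 25
  pm25 <- planted_model(gamma = g, level1_residual_sd = 0,
                        random_effect_sds = c(b0 = 0, b1 = 0, b2 = 0))
  expect_true(all(generate_ratings(row, psd, pm25, seed = 1)$rating == 20))

  expect_error(generate_ratings(row, psd[-3, ], pm8, seed = 1), "0")
})

test_that("planted level-1 coefficients round-trip through the OLS refit", {
  psd <- data.frame(brightness = -2:2, psd_db = c(-27.1, -26.4, -24.0,
                                                  -21.9, -20.2))
  row <- data.frame(menstrual_pain = 80, somatic_symptoms = 5,
                    bladder_pain = 30)
  pm <- planted_model(level1_residual_sd = 0,
                      random_effect_sds = c(b0 = 0, b1 = 0, b2 = 0))
  r <- generate_ratings(row, psd, pm, seed = 4, clip = FALSE)
  fit <- fit_level1(r$rating, r$brightness, psd$psd_db)
  expect_equal(fit$b0, attr(r, "b0"), tolerance = 1e-10)
  expect_equal(fit$b1, attr(r, "b1"), tolerance = 1e-10)
  expect_equal(fit$b2, attr(r, "b2"), tolerance = 1e-10)
})

test_that("the EEG path realizes the planted dB model at the driver electrode", {
  # noisy sessions, subject slope variance off: the per-participant fitted
  # slope scatters around the planted 2.05 dB/step only through level-1 noise
  pm <- planted_model(ssvep_base_subject_sd = 2,
                      ssvep_slope_subject_sd = 0)
  sp <- session_spec()
  slopes <- vapply(1:8, function(i) {
    rec <- generate_session_eeg(data.frame(participant = sprintf("p%d", i)),
                                pm, sp, seed = 100 + i)
    es <- reject_epochs(epoch_blocks(preprocess_recording(rec)))
    es <- apply_laplacian(es, build_csd_kernel(montage_1020()))
    tab <- build_psd_table(list(p = es))
    oz <- tab[tab$electrode == "Oz", ]
    unname(coef(lm(psd_db ~ brightness, oz))[2])
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2.05), 4 * se + 0.05)
})
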
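test_that("brightness codes center to -2..2", {
  expect_equal(center_brightness(1:5), -2:2)
  expect_equal(center_brightness(c(5, 1, 3, 2, 4)), c(2, -2, 0, -1, 1))
  expect_equal(center_brightness(-2:2), -2:2)
  expect_equal(center_brightness(c(1, 30, 60, 90, 120)), -2:2)
  expect_error(center_brightness(1:4), "5")
})

test_that("first-level OLS matches the normal-equations oracle", {
  x <- -2:2
  f <- fit_level1(3 + 2 * x, x)
  expect_equal(f$b0, 3)
  expect_equal(f$b1, 2)
  expect_equal(f$residual_df, 3)

  fc <- fit_level1(rep(4, 5), x, psd = c(1, 4, 2, 5, 3))
  expect_equal(fc$b1, 0, tolerance = 1e-12)
  expect_equal(fc$b2, 0, tolerance = 1e-12)
  expect_equal(fc$residual_df, 2)

  set.seed(6)
  y <- rnorm(5); psd <- rnorm(5)
  f2 <- fit_level1(y, x, psd)
  X <- cbind(1, x, psd - mean(psd))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f2$b0, f2$b1, f2$b2), as.numeric(beta), tolerance = 1e-10)
  # closed form for the brightness-only model: b1 = sum(xy)/10, b0 = mean(y)
  f3 <- fit_level1(y, x)
  expect_equal(f3$b1, sum(x * y) / 10, tolerance = 1e-12)
  expect_equal(f3$b0, mean(y), tolerance = 1e-12)

  # PSD collinear with brightness: flagged, not silently fit
  expect_false(fit_level1(y, x, psd = 2 * x)$ok)
})

test_that("second-level model comparison matches a hand-built oracle", {
  # 8-participant toy, verified against explicit SSE(full) vs SSE(reduced)
  set.seed(10)
  mod <- tibble::tibble(
    participant = sprintf("p%d", 1:8),
    menstrual_pain = c(10, 80, 45, 60, 20, 95, 50, 30),
    somatic_symptoms = c(0, 4, 2, 7, 1, 3, 5, 2),
    bladder_pain = c(0, 40, 10, 25, 5, 60, 15, 0)
  )
  y <- c(4.1, 9.8, 6.5, 8.2, 5.0, 11.3, 7.7, 5.9)
  names(y) <- mod$participant
  out <- fit_level2(y, mod)

  d <- as.data.frame(scale(mod[, -1], scale = FALSE))
  d$y <- y
  full <- lm(y ~ menstrual_pain + somatic_symptoms + bladder_pain, d)
  sse <- function(m) sum(resid(m)^2)
  mse <- sse(full) / df.residual(full)
  drops <- c(
    Intercept = sse(lm(y ~ 0 + menstrual_pain + somatic_symptoms +
                         bladder_pain, d)) - sse(full),
    `Menstrual Pain` = sse(lm(y ~ somatic_symptoms + bladder_pain, d)) -
      sse(full),
    `Somatic Symptoms` = sse(lm(y ~ menstrual_pain + bladder_pain, d)) -
      sse(full),
    `Bladder Pain` = sse(lm(y ~ menstrual_pain + somatic_symptoms, d)) -
      sse(full)
  )
  for (tm in names(drops)) {
    row <- out[out$term == tm, ]
    dd <- unname(drops[tm])
    expect_equal(row$ss, dd, tolerance = 1e-8)
    expect_equal(row$mse, mse, tolerance = 1e-10)
    expect_equal(row$f, dd / mse, tolerance = 1e-8)
    expect_equal(row$eta_p2, dd / (dd + 4 * mse), tolerance = 1e-8)
  }
  expect_equal(out$b, unname(coef(full)[c(1, 2, 3, 4)]), tolerance = 1e-10)
  expect_equal(out$df_den[1], 4)  # N - 4

  # constant coefficient: all moderator SS vanish, intercept is the constant
  yc <- setNames(rep(6.25, 8), mod$participant)
  outc <- fit_level2(yc, mod)
  expect_equal(outc$b[outc$term == "Intercept"], 6.25)
  expect_true(all(outc$ss[outc$term != "Intercept"] < 1e-18))

  expect_error(fit_level2(y[1:5], mod[1:5, ]), "too few")
})

test_that("effect-size and interval helpers reproduce printed statistics", {
  # identities recomputable from a published multilevel results table
  expect_equal(round(eta_p2(617.64, 146, 1.22), 2), 0.78)
  expect_equal(round(eta_p2(134.33, 143, 14.92), 2), 0.06)
  expect_equal(eta_p2(0, 146, 1.22), 0)
  expect_equal(round(f_from_ss(134.33, 1, 14.92), 2), 9.00)
  expect_equal(round(f_from_ss(0.83, 1, 0.17), 2), 4.88)
  expect_equal(f_from_ss(0, 1, 3.3), 0)
  expect_error(eta_p2(1, 10, 0), "positive")
  expect_error(f_from_ss(1, 1, -2), "positive")

  ci <- ci_from_se(2.05, 0.09, 146)
  expect_equal(round(unname(ci), 2), c(1.87, 2.23))
  expect_equal(unname(ci_from_se(5, 0, 100)), c(5, 5))
  expect_equal(unname(ci),
               2.05 + c(-1, 1) * qt(0.975, 146) * 0.09, tolerance = 1e-12)
})

test_that("FDR adjustment equals brute-force step-up over the family", {
  p <- setNames(rep(0.01, 32), paste0("e", 1:32))
  names(p)[32] <- "Oz"
  adj <- fdr_adjust(p)
  expect_true(all(adj[paste0("e", 1:31)] == 0.01))
  expect_true(is.na(adj["Oz"]))

  set.seed(12)
  p2 <- setNames(c(runif(31)^2, 0.5), c(paste0("e", 1:31), "Oz"))
  adj2 <- fdr_adjust(p2)
  expect_equal(unname(adj2[paste0("e", 1:31)]),
               bh_stepup(unname(p2[paste0("e", 1:31)])), tolerance = 1e-12)

  single <- fdr_adjust(c(e1 = 0.037, Oz = 0.2))
  expect_equal(unname(single["e1"]), 0.037)
  expect_error(fdr_adjust(c(e1 = 1.2, Oz = 0.1)), "\\[0, 1\\]")
})

test_that("bootstrap correlations behave at the degenerate extremes", {
  x <- 1:20
  perfect <- bootstrap_corr(x, 2 * x + 3, B = 200, seed = 1)
  expect_equal(perfect$r, 1)
  expect_equal(c(perfect$ci_lo, perfect$ci_hi), c(1, 1))
  expect_lt(perfect$p, 1e-10)
  expect_equal(bootstrap_corr(x, -x, B = 50, seed = 1)$r, -1)

  set.seed(20)
  xr <- rnorm(20); yr <- 0.5 * xr + rnorm(20)
  bc <- bootstrap_corr(xr, yr, B = 2000, seed = 5)
  expect_lt(bc$ci_lo, bc$r)
  expect_gt(bc$ci_hi, bc$r)
  # p agrees with the classical t test of the correlation
  expect_equal(bc$p, cor.test(xr, yr)$p.value, tolerance = 1e-10)
  # seeded: reproducible
  bc2 <- bootstrap_corr(xr, yr, B = 2000, seed = 5)
  expect_identical(bc[c("ci_lo", "ci_hi")], bc2[c("ci_lo", "ci_hi")])

  expect_error(bootstrap_corr(1:2, 2:3), "3")
  expect_error(bootstrap_corr(rep(1, 10), rnorm(10)), "variance")
})

test_that("noise-free planted slopes pass through both levels exactly", {
  pm <- planted_model(ssvep_base_subject_sd = 0, ssvep_slope_subject_sd = 0,
                      psd_noise_sd = 0)
  cohort <- generate_cohort(cohort_params(n_participants = 12, seed = 3))
  psd <- simulate_psd_table(cohort, pm, seed = 4)
  res <- analyze_brightness(psd)
  g10 <- res$level2$b[res$level2$model == "Brightness" &
                        res$level2$term == "Intercept"]
  g00 <- res$level2$b[res$level2$model == "Intercept" &
                        res$level2$term == "Intercept"]
  expect_equal(g10, 2.05, tolerance = 1e-10)
  expect_equal(g00, -23.76, tolerance = 1e-10)
})

test_that("emitted second-level rows satisfy the reporting identities", {
  study <- simulate_study(cohort_params(n_participants = 40), seed = 77)
  fit <- analyze_moderation(study$psd, study$ratings, study$covariates)
  l2 <- fit$level2
  expect_equal(l2$f, l2$ss / (l2$df_num * l2$mse), tolerance = 1e-10)
  expect_equal(l2$eta_p2, l2$ss / (l2$ss + l2$df_den * l2$mse),
               tolerance = 1e-10)
  expect_equal(l2$ci_lo, l2$b - qt(0.975, l2$df_den) * l2$se,
               tolerance = 1e-10)
  expect_equal(l2$ci_hi, l2$b + qt(0.975, l2$df_den) * l2$se,
               tolerance = 1e-10)
  expect_true(all(l2$df_den == 40 - 4))
  # t^2 = F for 1-df model comparisons
  expect_equal((l2$b / l2$se)^2, l2$f, tolerance = 1e-8)
})
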
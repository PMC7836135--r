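#' Analysis 1: brightness modulation of SSVEP power
#'
#' For every electrode, fits the first-level regression of 25 Hz dB power
#' on centered brightness per participant, then intercept-only
#' second-level models of the first-level intercepts (mean PSD) and slopes
#' (dB per brightness step). P-values are FDR-adjusted per model across
#' the exploratory (non-a-priori) electrodes.
#'
#' @param psd_table Tibble (participant, electrode, brightness, psd_db).
#' @param a_priori Channel excluded from the FDR family.
#' @return List with `level1` (participant x electrode coefficients) and
#'   `level2` (one row per electrode x model, `model` in
#'   `{"Intercept", "Brightness"}`).
#' @export
analyze_brightness <- function(psd_table, a_priori = "Oz") {
  l1 <- psd_table |>
    dplyr::group_by(.data$participant, .data$electrode) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_level1(d$psd_db, d$brightness)
      tibble::tibble(b0 = f$b0, b1 = f$b1, ok = f$ok)
    }) |>
    dplyr::ungroup()

  l2 <- dplyr::bind_rows(lapply(unique(l1$electrode), function(el) {
    sub <- l1[l1$electrode == el & l1$ok, ]
    dplyr::bind_rows(lapply(c(Intercept = "b0", Brightness = "b1"),
                            function(cf) {
      fit_level2(stats::setNames(sub[[cf]], sub$participant))
    }), .id = "model") |>
      dplyr::mutate(electrode = el, .before = 1)
  }))
  l2 <- add_fdr(l2, a_priori)
  list(level1 = l1, level2 = l2)
}

#' Analysis 2: moderated unpleasantness-brightness-excitation models
#'
#' For every electrode, fits the first-level regression of unpleasantness
#' ratings on centered brightness and the within-participant-centered PSD
#' predictor, then second-level moderation models of each first-level
#' coefficient (Intercept, Brightness slope, PSD slope) on the grand-mean
#' centered moderators (menstrual pain, somatic symptoms, bladder pain).
#' Participants with a failed or rank-deficient first-level fit, or
#' missing moderators, are dropped listwise. P-values are FDR-adjusted per
#' (model, term) across the exploratory electrodes.
#'
#' @param psd_table Tibble (participant, electrode, brightness, psd_db).
#' @param ratings Tibble (participant, brightness, rating).
#' @param covariates Tibble (participant, menstrual_pain,
#'   somatic_symptoms, bladder_pain).
#' @param a_priori Channel excluded from the FDR family.
#' @param center_psd Passed to [fit_level1()].
#' @return List with `level1`, `level2` and `dropped` (participants
#'   excluded per electrode).
#' @export
analyze_moderation <- function(psd_table, ratings, covariates,
                               a_priori = "Oz",
                               center_psd = "participant") {
  dat <- dplyr::inner_join(psd_table, ratings,
                           by = c("participant", "brightness"))
  l1 <- dat |>
    dplyr::group_by(.data$participant, .data$electrode) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_level1(d$rating, d$brightness, d$psd_db,
                      center_psd = center_psd)
      tibble::tibble(b0 = f$b0, b1 = f$b1, b2 = f$b2, ok = f$ok)
    }) |>
    dplyr::ungroup()

  dropped <- l1[!l1$ok, c("participant", "electrode")]
  l2 <- dplyr::bind_rows(lapply(unique(l1$electrode), function(el) {
    sub <- l1[l1$electrode == el & l1$ok, ]
    dplyr::bind_rows(
      lapply(c(Intercept = "b0", Brightness = "b1", PSD = "b2"),
             function(cf) {
        fit_level2(stats::setNames(sub[[cf]], sub$participant), covariates)
      }), .id = "model") |>
      dplyr::mutate(electrode = el, .before = 1)
  }))
  l2 <- add_fdr(l2, a_priori)
  list(level1 = l1, level2 = l2, dropped = dropped)
}

# Per-(model, term) BH adjustment across exploratory electrodes.
add_fdr <- function(l2, a_priori) {
  l2 |>
    dplyr::group_by(.data$model, .data$term) |>
    dplyr::group_modify(function(d, key) {
      d$p_fdr <- fdr_adjust(stats::setNames(d$p, d$electrode), a_priori)
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("electrode", "model", "term")
}

#' Bootstrapped correlation table of the moderating variables
#'
#' Pairwise Pearson correlations among menstrual pain, somatic symptoms
#' and bladder pain with percentile-bootstrap confidence intervals, plus
#' descriptive statistics of the first variable of each pair.
#'
#' @param covariates Tibble with the three moderator columns.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return A tibble, one row per pair.
#' @export
moderator_corr_table <- function(covariates, B = 2000, seed = 1L) {
  pairs <- list(
    c("menstrual_pain", "bladder_pain"),
    c("bladder_pain", "somatic_symptoms"),
    c("somatic_symptoms", "menstrual_pain")
  )
  dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
    v <- pairs[[i]]
    bc <- bootstrap_corr(covariates[[v[1]]], covariates[[v[2]]], B = B,
                         seed = seed + i)
    x <- covariates[[v[1]]]
    tibble::tibble(
      variable_1 = v[1], variable_2 = v[2],
      r = bc$r, ci_lo = bc$ci_lo, ci_hi = bc$ci_hi, p = bc$p,
      m = mean(x), sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)),
      min = min(x), max = max(x)
    )
  }))
}
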
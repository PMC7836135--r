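#' Mean-center ordered brightness codes
#'
#' Maps the five ordered brightness levels to the centered codes
#' -2, -1, 0, 1, 2 (rank-based: the levels are ordinal intensity codes).
#' Already-centered codes pass through unchanged.
#'
#' @param codes Numeric vector whose distinct values are the five ordered
#'   levels.
#' @return The vector with levels recoded to -2..2.
#' @examples
#' center_brightness(c(1, 2, 3, 4, 5))
#' @export
center_brightness <- function(codes) {
  lev <- sort(unique(codes))
  if (length(lev) != 5)
    stop(sprintf("expected 5 brightness levels, got %d", length(lev)))
  centered <- c(-2, -1, 0, 1, 2)
  centered[match(codes, lev)]
}

#' First-level (within-participant) regression
#'
#' Ordinary least squares of one participant's five per-block values on
#' centered brightness (and, for the unpleasantness model, the
#' within-participant-centered PSD predictor). With brightness alone the
#' fit has the closed form b1 = sum(x*y)/10, b0 = mean(y).
#'
#' @param y Response per block (dB power, or GBS rating).
#' @param brightness Brightness codes per block (centered, or any 5
#'   ordered levels).
#' @param psd Optional PSD predictor per block (dB).
#' @param center_psd How to center the PSD predictor: within this
#'   participant (default, so the intercept is the participant's mean
#'   response) or not at all (for predictors centered elsewhere).
#' @return A list: `b0`, `b1`, `b2` (NA if no PSD predictor),
#'   `residual_df`, `ok` (FALSE on rank deficiency), `n`.
#' @export
fit_level1 <- function(y, brightness, psd = NULL,
                       center_psd = c("participant", "none")) {
  center_psd <- match.arg(center_psd)
  keep <- is.finite(y) & is.finite(brightness) &
    (if (is.null(psd)) TRUE else is.finite(psd))
  y <- y[keep]
  x1 <- brightness[keep]
  if (length(unique(x1)) == 5) x1 <- center_brightness(x1)
  X <- cbind(intercept = 1, brightness = x1)
  if (!is.null(psd)) {
    x2 <- psd[keep]
    if (center_psd == "participant") x2 <- x2 - mean(x2)
    X <- cbind(X, psd = x2)
  }
  p <- ncol(X)
  if (length(y) < p + 1)
    return(list(b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                residual_df = NA_integer_, ok = FALSE, n = length(y)))
  fit <- stats::lm.fit(X, y)
  ok <- fit$rank == p
  cf <- fit$coefficients
  list(b0 = unname(cf["intercept"]), b1 = unname(cf["brightness"]),
       b2 = if (is.null(psd)) NA_real_ else unname(cf["psd"]),
       residual_df = length(y) - p, ok = ok, n = length(y))
}

#' Partial eta-squared from a model comparison
#'
#' `ss / (ss + df_den * mse)`: the effect sum of squares against the
#' full-model error.
#'
#' @param ss Effect sum of squares (>= 0).
#' @param df_den Denominator (error) degrees of freedom.
#' @param mse Full-model mean squared error (> 0).
#' @return Proportion of variance.
#' @examples
#' eta_p2(617.64, 146, 1.22) # 0.78
#' @export
eta_p2 <- function(ss, df_den, mse) {
  stopifnot(all(ss >= 0))
  if (any(mse <= 0)) stop("mse must be positive")
  ss / (ss + df_den * mse)
}

#' F statistic from a model-comparison sum of squares
#'
#' @param ss Effect sum of squares.
#' @param df_num Numerator degrees of freedom (default 1).
#' @param mse Full-model mean squared error (> 0).
#' @return F value `(ss/df_num)/mse`.
#' @examples
#' f_from_ss(134.33, 1, 14.92) # 9.00
#' @export
f_from_ss <- function(ss, df_num = 1, mse) {
  stopifnot(all(df_num >= 1))
  if (any(mse <= 0)) stop("mse must be positive")
  (ss / df_num) / mse
}

#' Confidence interval from an estimate and its standard error
#'
#' `b +/- t((1+level)/2, df_den) * se`.
#'
#' @param b Estimate.
#' @param se Standard error (>= 0).
#' @param df_den Degrees of freedom.
#' @param level Confidence level.
#' @return Numeric vector `c(lo, hi)` (or a 2-column matrix for vector
#'   input).
#' @examples
#' ci_from_se(2.05, 0.09, 146) # c(1.87, 2.23) at 2 dp
#' @export
ci_from_se <- function(b, se, df_den, level = 0.95) {
  stopifnot(all(se >= 0))
  tq <- stats::qt((1 + level) / 2, df_den)
  if (length(b) == 1) c(lo = b - tq * se, hi = b + tq * se)
  else cbind(lo = b - tq * se, hi = b + tq * se)
}

#' Second-level (between-participant) moderation regression
#'
#' Regresses one first-level coefficient per participant on the grand-mean
#' centered moderators (or on an intercept alone when `moderators` is
#' `NULL`). Each term's sum of squares comes from a model comparison (full
#' versus single-term-deleted, equivalent to Type III with 1-df terms);
#' the mean squared error comes from the full model. Emits one row per
#' term with b, SE, 95% CI, SS, MSE, F, p and partial eta-squared.
#'
#' Participants with a missing coefficient or missing moderator values are
#' dropped listwise; the denominator df reflects the included N.
#'
#' @param coef_values Named numeric vector (participant -> first-level
#'   coefficient).
#' @param moderators Data frame with `participant` and the moderator
#'   columns, or `NULL` for the intercept-only model.
#' @param moderator_names Columns of `moderators` to use.
#' @param level Confidence level for the CI.
#' @return A tibble, one row per term.
#' @export
fit_level2 <- function(coef_values, moderators = NULL,
                       moderator_names = c("menstrual_pain",
                                           "somatic_symptoms",
                                           "bladder_pain"),
                       level = 0.95) {
  y <- coef_values[is.finite(coef_values)]
  if (!is.null(moderators)) {
    stopifnot("participant" %in% names(moderators),
              all(moderator_names %in% names(moderators)))
    mod <- moderators[match(names(y), moderators$participant),
                      moderator_names, drop = FALSE]
    cc <- stats::complete.cases(mod)
    y <- y[cc]
    M <- scale(as.matrix(mod[cc, , drop = FALSE]), center = TRUE,
               scale = FALSE)
    X <- cbind(Intercept = 1, M)
  } else {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "Intercept"))
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop(sprintf("too few participants (N = %d) for %d terms",
                               n, p))
  fit <- stats::lm.fit(X, y)
  sse_full <- sum(fit$residuals^2)
  df_den <- n - p
  mse <- sse_full / df_den
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(mse * diag(XtX_inv))

  ss <- vapply(seq_len(p), function(j) {
    Xr <- X[, -j, drop = FALSE]
    sse_red <- if (ncol(Xr) == 0) sum(y^2) else
      sum(stats::lm.fit(Xr, y)$residuals^2)
    sse_red - sse_full
  }, numeric(1))
  ss <- pmax(ss, 0)

  b <- fit$coefficients
  fstat <- f_from_ss(ss, 1, mse)
  ci <- ci_from_se(unname(b), se, df_den, level)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1)
  term_labels <- c(Intercept = "Intercept",
                   menstrual_pain = "Menstrual Pain",
                   somatic_symptoms = "Somatic Symptoms",
                   bladder_pain = "Bladder Pain")
  terms <- colnames(X)
  lbl <- term_labels[terms]
  lbl[is.na(lbl)] <- terms[is.na(lbl)]
  tibble::tibble(
    term = unname(lbl),
    b = unname(b), se = unname(se),
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    ss = ss, mse = mse, df_num = 1L, df_den = df_den,
    f = fstat, p = stats::pf(fstat, 1, df_den, lower.tail = FALSE),
    eta_p2 = eta_p2(ss, df_den, mse),
    n = n
  )
}

#' Benjamini-Hochberg FDR adjustment across exploratory electrodes
#'
#' Step-up false discovery rate adjustment over the exploratory
#' electrodes; the a-priori channel is excluded from the family and
#' reported unadjusted (`NA` in the adjusted vector).
#'
#' @param pvals Named numeric vector of p-values, one per electrode.
#' @param a_priori Label(s) excluded from the family.
#' @return Named vector of adjusted p-values (`NA` at the a-priori
#'   channel).
#' @export
fdr_adjust <- function(pvals, a_priori = "Oz") {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  names(out) <- names(pvals)
  fam <- setdiff(names(pvals), a_priori)
  out[fam] <- stats::p.adjust(pvals[fam], method = "BH")
  out
}

#' Pearson correlation with a percentile bootstrap confidence interval
#'
#' @param x,y Paired numeric vectors (n >= 3, non-zero variance).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A list: `r`, `ci_lo`, `ci_hi`, `p` (two-tailed, from the t
#'   transform of r), `n`, `B`.
#' @export
bootstrap_corr <- function(x, y, B = 2000, seed = 1L, level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                        na.rm = TRUE, names = FALSE)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci_lo = qs[1], ci_hi = qs[2],
       p = 2 * stats::pt(-abs(tval), n - 2), n = n, B = B)
}
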
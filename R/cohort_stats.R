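# Cohort-level statistics: audiograms and LFPTA, correlations, univariate
# regression screening, dependent-correlation comparison, paired tests.

#' Audiogram
#'
#' @param thresholds Named numeric vector mapping frequency (Hz, as names)
#'   to threshold in dB HL, each within `[-10, 130]`.
#' @return Object of class `audiogram`.
#' @examples
#' audiogram(c("125" = 40, "250" = 50, "500" = 60))
#' @export
audiogram <- function(thresholds) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  if (any(thresholds < -10 | thresholds > 130)) {
    stop("thresholds must lie in [-10, 130] dB HL", call. = FALSE)
  }
  structure(list(thresholds = thresholds), class = "audiogram")
}

#' Low-frequency pure-tone average (125, 250, 500 Hz)
#'
#' @param x An [audiogram()]; must contain thresholds at 125, 250 and
#'   500 Hz.
#' @return Arithmetic mean of the three thresholds, dB HL.
#' @export
lfpta <- function(x) {
  stopifnot(inherits(x, "audiogram"))
  need <- c("125", "250", "500")
  if (!all(need %in% names(x$thresholds))) {
    stop("audiogram must contain 125, 250 and 500 Hz thresholds",
         call. = FALSE)
  }
  mean(x$thresholds[need])
}

#' LFPTA shift (hearing loss) between two audiograms
#'
#' @param pre,post Pre- and postoperative [audiogram()]s.
#' @return `lfpta(post) - lfpta(pre)` in dB HL; positive values are hearing
#'   loss.
#' @export
lfpta_shift <- function(pre, post) {
  lfpta(post) - lfpta(pre)
}

#' Sample-size-weighted pooled mean of group means
#'
#' @param means Group means.
#' @param ns Group sizes.
#' @return `sum(means * ns) / sum(ns)`.
#' @export
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns > 0))
  sum(means * ns) / sum(ns)
}

#' Correlation with two-sided p value
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p`, `n`, `method`. Zero-variance input
#'   yields `NA` estimates with a warning.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(estimate = NA_real_, p = NA_real_, n = length(x),
                method = method))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Univariate ordinary-least-squares fit
#'
#' `y ~ x` with slope/intercept estimates, Pearson r, the slope's two-sided
#' p value, and 95% confidence intervals for both coefficients.
#'
#' @param x Predictor (e.g. largest CM drop, dB).
#' @param y Response (e.g. LFPTA shift, dB HL).
#' @return List with `slope`, `intercept`, `r`, `p`, `slope_ci`,
#'   `intercept_ci` (each a length-2 vector), `n`.
#' @export
univariate_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("degenerate design: predictor has zero variance", call. = FALSE)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, slope_ci = c(NA_real_, NA_real_),
                intercept_ci = c(NA_real_, NA_real_), n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(sign(stats::coef(fit)[2]) * sqrt(sm$r.squared)),
    p = unname(sm$coefficients[2, 4]),
    slope_ci = unname(ci["x", ]),
    intercept_ci = unname(ci["(Intercept)", ]),
    n = length(x)
  )
}

#' Pearson-Filon z test for two overlapping dependent correlations
#'
#' Compares `r12` and `r13` measured on the same sample of size `n`, where
#' variable 1 is shared (e.g. LFPTA shift correlated with the 250-Hz drop
#' and with the 500-Hz drop), using the Pearson-Filon (1898) statistic:
#'
#' `z = (r12 - r13) * sqrt(n) / sqrt((1-r12^2)^2 + (1-r13^2)^2 - 2k)`
#'
#' with `k = r23 (1 - r12^2 - r13^2) - (r12 r13 / 2)(1 - r12^2 - r13^2 -
#' r23^2)`. `r23` is the correlation between the two non-shared variables;
#' it must be supplied (or computed from the cohort) because it enters the
#' dependence correction.
#'
#' @param r12,r13 The two correlations being compared, each in `(-1, 1)`.
#' @param r23 Correlation between variables 2 and 3, in `(-1, 1)`.
#' @param n Sample size (> 3).
#' @return List with `z` and the two-sided normal `p`.
#' @export
pearson_filon_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (n <= 3) stop("need n > 3", call. = FALSE)
  k <- r23 * (1 - r12^2 - r13^2) -
    0.5 * (r12 * r13) * (1 - r12^2 - r13^2 - r23^2)
  denom <- (1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k
  if (denom <= 0) stop("degenerate correlation configuration", call. = FALSE)
  z <- (r12 - r13) * sqrt(n) / sqrt(denom)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Paired two-sided t test
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `p`, `mean_diff`, `n`. Identical vectors return
#'   `t = 0, p = 1` with a flag instead of erroring on zero variance.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero-variance differences", call. = FALSE)
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, p = if (t == 0) 1 else 0, mean_diff = mean(d),
                n = length(x)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(x))
}

#' Univariate screening of insertion features against LFPTA shift
#'
#' Regresses the LFPTA shift on each standard trajectory feature (drop
#' count, largest drop dB, starting amplitude, final/max %), per stimulus
#' frequency, plus the pattern type as a categorical predictor (indicator
#' coding, Type A reference, F-test p). No multiple-testing correction is
#' applied by default; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param cohort Data frame with one row per case: `lfpta_shift` plus, per
#'   frequency `f` in `freqs`, columns `n_drops_<f>`, `largest_drop_db_<f>`,
#'   `start_amp_uv_<f>`, `final_over_max_pct_<f>`, `pattern_<f>`.
#' @param freqs Frequencies to screen (default `c(250, 500)`).
#' @param adjust P-value adjustment method (default `"none"`).
#' @return Data frame with `feature`, `freq_hz`, `coefficient` (OLS slope;
#'   `NA` for the categorical pattern), `r`, `p`, and `p_adj`.
#' @export
screen_predictors <- function(cohort, freqs = c(250, 500), adjust = "none") {
  stopifnot(is.data.frame(cohort), "lfpta_shift" %in% names(cohort))
  shift <- cohort$lfpta_shift
  numeric_features <- c("n_drops", "largest_drop_db", "start_amp_uv",
                        "final_over_max_pct")
  rows <- list()
  for (f in freqs) {
    for (feat in numeric_features) {
      col <- paste0(feat, "_", f)
      if (!col %in% names(cohort)) {
        message(sprintf("column `%s` missing; row skipped", col))
        next
      }
      fit <- univariate_fit(cohort[[col]], shift)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, freq_hz = f, coefficient = fit$slope, r = fit$r,
        p = fit$p)
    }
    pcol <- paste0("pattern_", f)
    if (pcol %in% names(cohort)) {
      pat <- stats::relevel(factor(cohort[[pcol]], levels = c("A", "B", "C")),
                            ref = "A")
      if (nlevels(droplevels(pat)) > 1L) {
        fit <- stats::lm(shift ~ pat)
        an <- stats::anova(fit)
        r2 <- summary(fit)$r.squared
        rows[[length(rows) + 1L]] <- data.frame(
          feature = "pattern", freq_hz = f, coefficient = NA_real_,
          r = sqrt(r2), p = an$`Pr(>F)`[1])
      } else {
        message(sprintf("`%s` has a single level; row skipped", pcol))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
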
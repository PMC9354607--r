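# Cohort statistics: LFPTA, correlations, regression, Pearson-Filon,
# paired t, predictor screening.

test_that("LFPTA is the mean of the three low-frequency thresholds", {
  expect_equal(lfpta(audiogram(c("125" = 40, "250" = 50, "500" = 60))), 50)
  expect_equal(lfpta(audiogram(c("125" = 35, "250" = 35, "500" = 35,
                                 "1000" = 80))), 35)
  expect_error(lfpta(audiogram(c("250" = 50, "500" = 60))), "125")
  expect_error(audiogram(c("125" = 150)), "\\[-10, 130\\]")
})

test_that("LFPTA shift is post minus pre, positive for hearing loss", {
  a <- audiogram(c("125" = 48.1, "250" = 48.1, "500" = 48.1))
  b <- audiogram(c("125" = 99.1, "250" = 99.1, "500" = 99.1))
  expect_equal(lfpta_shift(a, b), 51.0, tolerance = 1e-12)
  expect_equal(lfpta_shift(a, a), 0)
})

test_that("correlation wrapper matches expectations on constructed data", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x)$estimate, 1)
  expect_lt(correlate(x, -3 * x + 5)$estimate, -0.999)
  # Spearman is invariant to rank-preserving monotone transforms
  set.seed(31)
  y <- rnorm(30)
  x2 <- runif(30)
  r1 <- correlate(x2, y, method = "spearman")$estimate
  r2 <- correlate(exp(x2), y, method = "spearman")$estimate
  expect_equal(r1, r2)
  # null data keeps |r| small at large n
  set.seed(32)
  rn <- correlate(rnorm(1e4), rnorm(1e4))$estimate
  expect_lt(abs(rn), 0.05)
  expect_warning(cz <- correlate(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(cz$estimate))
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("univariate fit recovers an exact line with zero residual and a
           collapsing confidence interval", {
  x <- seq(0, 10, by = 0.5)
  y <- 7.1 + 0.37 * x
  fit <- suppressWarnings(univariate_fit(x, y))  # lm flags the perfect fit
  expect_equal(fit$slope, 0.37, tolerance = 1e-12)
  expect_equal(fit$intercept, 7.1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_lt(diff(fit$slope_ci), 1e-9)
  expect_warning(f2 <- univariate_fit(rep(2, 5), 1:5), "zero variance")
  expect_true(is.na(f2$slope))
})

test_that("Pearson-Filon z is zero at equal correlations, signed like their
           difference, and guards its domain", {
  for (r23 in c(-0.5, 0, 0.3, 0.8)) {
    expect_equal(pearson_filon_z(0.4, 0.4, r23, 34)$z, 0)
  }
  expect_gt(pearson_filon_z(0.58, 0.31, 0.5, 34)$z, 0)
  expect_lt(pearson_filon_z(0.31, 0.58, 0.5, 34)$z, 0)
  z1 <- pearson_filon_z(0.58, 0.31, 0.5, 34)
  expect_equal(z1$p, 2 * pnorm(-abs(z1$z)), tolerance = 1e-12)
  expect_error(pearson_filon_z(1, 0.3, 0.2, 34), "strictly inside")
  expect_error(pearson_filon_z(0.5, 0.3, 0.2, 3), "n > 3")
})

test_that("paired t handles identical, offset, and null data", {
  x <- rnorm(20)
  expect_warning(res <- paired_t(x, x), "zero-variance")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  set.seed(41)
  y <- x + 2 + rnorm(20, 0, 0.1)
  expect_lt(paired_t(x, y)$p, 1e-10)
  # null type-I behaviour
  set.seed(42)
  rej <- mean(replicate(2000, {
    a <- rnorm(15); b <- rnorm(15)
    paired_t(a, b)$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("predictor screening finds the driving feature and encodes the
           pattern type categorically", {
  set.seed(51)
  n <- 120
  drop250 <- rexp(n, 1 / 4)
  cohort <- data.frame(
    lfpta_shift = 7.1 + 0.37 * drop250 + rnorm(n, 0, 0.5),
    n_drops_250 = rpois(n, 2), largest_drop_db_250 = drop250,
    start_amp_uv_250 = rlnorm(n, log(10), 0.5),
    final_over_max_pct_250 = runif(n, 40, 100),
    pattern_250 = sample(c("A", "B", "C"), n, replace = TRUE),
    n_drops_500 = rpois(n, 2), largest_drop_db_500 = rexp(n, 1 / 9),
    start_amp_uv_500 = rlnorm(n, log(9), 0.5),
    final_over_max_pct_500 = runif(n, 40, 100),
    pattern_500 = sample(c("A", "B", "C"), n, replace = TRUE)
  )
  sc <- screen_predictors(cohort)
  expect_identical(nrow(sc), 10L)
  best <- sc[which.max(abs(sc$r)), ]
  expect_identical(best$feature, "largest_drop_db")
  expect_identical(best$freq_hz, 250)
  expect_true(all(c("pattern") %in% sc$feature))
  expect_true(all(is.na(sc$coefficient[sc$feature == "pattern"])))
  # no adjustment by default; BH available
  expect_equal(sc$p, sc$p_adj)
  sc_bh <- screen_predictors(cohort, adjust = "BH")
  expect_true(all(sc_bh$p_adj >= sc_bh$p - 1e-15))
  # missing feature columns are skipped with a message
  expect_message(sc2 <- screen_predictors(cohort[, -2]), "skipped")
  expect_identical(nrow(sc2), 9L)
})

test_that("an all-noise cohort rarely produces spurious hits without
           correction", {
  set.seed(61)
  any_hit <- replicate(60, {
    n <- 34
    cohort <- data.frame(
      lfpta_shift = rnorm(n, 20, 10),
      n_drops_250 = rpois(n, 2), largest_drop_db_250 = rexp(n, 1 / 3),
      start_amp_uv_250 = rlnorm(n, log(10), 0.5),
      final_over_max_pct_250 = runif(n, 40, 100)
    )
    any(screen_predictors(cohort, freqs = 250)$p < 0.05)
  })
  # 4 independent-ish tests at alpha=.05: most replicates stay clean
  expect_gt(mean(!any_hit), 0.7)
})

test_that("pooled mean weights group means by group size", {
  expect_equal(pooled_mean(c(59.4, 48.1), c(34, 14)), 2693 / 48)
  expect_equal(pooled_mean(c(10, 10), c(3, 97)), 10)
})
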
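# Synthetic-cochlea generator: excitation profile, waveform synthesis,
# determinism, tonotopic phenomenology, cohort generator.

test_that("excitation profile is unimodal, peaks slightly basal of the CF
           place, and decays faster apically", {
  p <- excitation_params()
  cf <- 400
  at_cf <- excitation_amplitude(cf, cf, p)
  basal <- excitation_amplitude(seq(cf - 200, cf - 60, by = 10), cf, p)
  expect_true(all(at_cf >= basal))
  # 90 degrees apical of the CF place the response is below half peak
  expect_lt(excitation_amplitude(cf + 90, cf, p), 0.5 * p$peak_uv)
  # asymmetry: basal rise shallower than apical fall
  d <- 30
  peak_angle <- cf - p$peak_offset_deg
  rise <- p$peak_uv - excitation_amplitude(peak_angle - d, cf, p)
  fall <- p$peak_uv - excitation_amplitude(peak_angle + d, cf, p)
  expect_lt(rise, fall)
  sym <- excitation_params(symmetric = TRUE)
  expect_equal(excitation_amplitude(peak_angle - d, cf, sym),
               excitation_amplitude(peak_angle + d, cf, sym))
  expect_error(excitation_params(peak_uv = -1), "positive")
  expect_error(excitation_params(basal_space_deg = 0), "positive")
})

test_that("geometry and script constructors enforce their invariants", {
  expect_error(cochlear_geometry(7.5, 396), "8.0")
  expect_error(cochlear_geometry(9.2, 10, basal_angle_deg = 20),
               "apical_angle_deg")
  g <- cochlear_geometry(9.2, 396, basal_angle_deg = 20)
  expect_identical(length(g$electrode_angles_deg), 22L)
  expect_true(all(diff(g$electrode_angles_deg) > 0))
  expect_equal(g$electrode_angles_deg[22], 396)
  expect_error(event_script(data.frame(step_index = 1,
                                       attenuation_fraction = 0)),
               "positive")
  s <- event_script(data.frame(step_index = 300,
                               attenuation_fraction = 0.5))
  expect_error(simulate_insertion(cochlear_geometry(9.2, 396), script = s,
                                  noise_sd_uv = 0, n_steps = 50),
               "within the insertion")
  expect_error(tone_burst(500, duration_ms = 2, ramp_ms = 1), "exceed")
})

test_that("identical seeds reproduce identical recordings; the caller's RNG
           stream is untouched", {
  g <- cochlear_geometry(9.2, apical_angle_deg = 396)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  a <- simulate_insertion(g, n_steps = 6, seed = 123, n_noise_pairs = 5)
  after <- rnorm(1)
  b <- simulate_insertion(g, n_steps = 6, seed = 123, n_noise_pairs = 5)
  expect_identical(a$steps, b$steps)
  expect_identical(a$noise_pairs, b$noise_pairs)
  expect_identical(before, after)
  c <- simulate_insertion(g, n_steps = 6, seed = 124, n_noise_pairs = 5)
  expect_false(identical(a$steps, c$steps))
})

test_that("condensation and rarefaction waveforms are exact negations when
           noiseless", {
  g <- cochlear_geometry(9.2, apical_angle_deg = 396)
  sim <- simulate_insertion(g, noise_sd_uv = 0, n_steps = 5)
  for (st in sim$steps) {
    for (f in names(st)) {
      expect_identical(st[[f]]$cond$samples, -st[[f]]$rare$samples)
    }
  }
})

test_that("insertion traces show the two tonotopic phenotypes: joint rise in
           large cochleas, terminal 500-Hz decline in small/deep ones", {
  large <- simulate_insertion(cochlear_geometry(9.9, 396), noise_sd_uv = 0,
                              n_steps = 50)
  tr_l <- build_insertion_trace(large)
  expect_identical(which.max(tr_l$amp_500), 50L)
  expect_identical(which.max(tr_l$amp_250), 50L)
  small <- simulate_insertion(cochlear_geometry(8.4, 430), noise_sd_uv = 0,
                              n_steps = 50)
  tr_s <- build_insertion_trace(small)
  expect_lt(which.max(tr_s$amp_500), 45L)
  expect_identical(which.max(tr_s$amp_250), 50L)
  expect_gt(largest_drop_db(tr_s, 500), to_db(1 / 0.7))  # a >30% decline
  expect_equal(largest_drop_db(tr_s, 250), 0)
})

test_that("single-sweep analysis noise floor sits near 1 uV under the
           default noise calibration", {
  g <- cochlear_geometry(9.2, apical_angle_deg = 396)
  sim <- simulate_insertion(g, n_steps = 2, seed = 5, n_noise_pairs = 400)
  tr <- build_insertion_trace(sim)
  nf <- attr(tr, "noise_floor")
  expect_equal(nf[["500"]]$mean_uv, 1.0, tolerance = 0.1)
})

test_that("cohort generator recovers its linear model exactly when the
           residual is switched off", {
  p <- cohort_params()
  p$resid_sd_db <- 0
  cases <- simulate_cohort(60, p, seed = 21)
  tab <- cohort_table(cases)
  fit <- suppressWarnings(  # lm flags the perfect fit
    univariate_fit(tab$largest_drop_db_250, tab$lfpta_shift))
  expect_equal(fit$slope, 0.37, tolerance = 1e-6)
  expect_equal(fit$intercept, 7.1, tolerance = 1e-6)
  # lfpta_shift column is exactly post minus pre LFPTA
  expect_equal(tab$lfpta_shift, tab$post_lfpta - tab$pre_lfpta,
               tolerance = 1e-12)
})

test_that("with no trauma events every shift equals the intercept (up to
           any CF-crossing-driven 250-Hz drop)", {
  p <- cohort_params()
  p$resid_sd_db <- 0
  p$event_rate <- 0
  cases <- simulate_cohort(40, p, seed = 22)
  tab <- cohort_table(cases)
  no250drop <- tab$largest_drop_db_250 == 0
  expect_true(mean(no250drop) > 0.9)  # 250-Hz place is rarely crossed
  expect_equal(tab$lfpta_shift[no250drop],
               rep(7.1, sum(no250drop)), tolerance = 1e-9)
})

test_that("cohort generator refuses degenerate sizes", {
  expect_error(simulate_cohort(2), ">= 3")
})
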
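# Insertion-trajectory metrics: drop detection, magnitudes, counts,
# pattern typing, trauma-vs-CF-crossing labels.

test_that("drop detector reproduces hand-enumerated event structure", {
  tr <- make_trace_500(c(2, 5, 10, 6, 9))
  ev <- detect_drops(tr, 500)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_uv, 10)
  expect_equal(ev$trough_uv, 6)
  expect_equal(ev$peak_step, 3L)
  expect_equal(ev$trough_step, 4L)
  expect_equal(ev$relative_drop, 0.40)

  # recovery re-arms the detector
  ev2 <- detect_drops(make_trace_500(c(10, 6, 10, 6)), 500)
  expect_identical(nrow(ev2), 2L)
  expect_equal(ev2$relative_drop, c(0.40, 0.40))
  expect_true(all(ev2$trough_step > ev2$peak_step))

  # monotone rising trace has no events
  expect_identical(nrow(detect_drops(make_trace_500(1:10), 500)), 0L)

  # all-zero trace warns and returns no events
  expect_warning(ev0 <- detect_drops(make_trace_500(rep(0, 5)), 500),
                 "all-zero")
  expect_identical(nrow(ev0), 0L)
})

test_that("incremental detector agrees with the exhaustive enumeration
           oracle on random traces", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_trace(20)
    got <- detect_drops(make_trace_500(a), 500)
    want <- oracle_detect_drops(a)
    expect_equal(got$peak_step, want$peak_step)
    expect_equal(got$trough_step, want$trough_step)
    expect_equal(got$peak_uv, want$peak_uv)
    expect_equal(got$trough_uv, want$trough_uv)
    expect_equal(got$relative_drop, want$relative_drop)
    expect_equal(got$drop_db, want$drop_db)
  }
})

test_that("drop detection is scale invariant and events stay disjoint", {
  set.seed(202)
  for (i in 1:25) {
    a <- random_trace(30)
    base <- detect_drops(make_trace_500(a), 500)
    for (c in c(0.01, 3, 1000)) {
      scaled <- detect_drops(make_trace_500(c * a), 500)
      expect_equal(scaled$peak_step, base$peak_step)
      expect_equal(scaled$trough_step, base$trough_step)
      expect_equal(scaled$relative_drop, base$relative_drop)
    }
    if (nrow(base) > 1) {
      # sub-threshold excursions are disjoint: troughs strictly advance and
      # peaks never move backwards
      expect_true(all(diff(base$trough_step) > 0))
      expect_true(all(diff(base$peak_step) >= 0))
    }
  }
})

test_that("largest drop measures peak to post-peak minimum in dB", {
  expect_equal(largest_drop_db(make_trace_500(c(2, 5, 10, 6, 9)), 500),
               20 * log10(10 / 6), tolerance = 1e-12)
  expect_equal(largest_drop_db(make_trace_500(c(1, 2, 3, 9)), 500), 0)
  # earliest maximum on ties makes the output deterministic
  expect_equal(largest_drop_db(make_trace_500(c(5, 10, 10, 4)), 500),
               20 * log10(10 / 4), tolerance = 1e-12)
  # largest event drop never exceeds the global peak-to-trough measure
  set.seed(303)
  for (i in 1:30) {
    a <- random_trace(25)
    tr <- make_trace_500(a)
    ev <- detect_drops(tr, 500)
    imax <- which.max(a)
    post <- ev[ev$peak_step >= imax, ]
    if (nrow(post) > 0) {
      expect_true(all(post$drop_db <= largest_drop_db(tr, 500) + 1e-9))
    }
  }
})

test_that("drop count applies the strict 2-uV absolute decrement", {
  # decrements 1 uV and 4 uV -> only one counts
  tr <- make_trace_500(c(2.8, 1.8, 10, 6, 9))
  ev <- detect_drops(tr, 500)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$peak_uv - ev$trough_uv, c(1, 4), tolerance = 1e-9)
  expect_identical(count_drops(tr, 500), 1L)
  expect_identical(count_drops(make_trace_500(1:5), 500), 0L)
  # decrement of exactly 2.0 uV is excluded (strict inequality)
  tr2 <- make_trace_500(c(6, 4))
  expect_equal(detect_drops(tr2, 500)$peak_uv -
                 detect_drops(tr2, 500)$trough_uv, 2)
  expect_identical(count_drops(tr2, 500), 0L)
})

test_that("insertion patterns classify by the A/B/C rules", {
  expect_identical(classify_pattern(make_trace_500(c(1, 3, 6, 9)), 500), "A")
  expect_identical(classify_pattern(make_trace_500(c(10, 8, 5, 3)), 500),
                   "B")
  expect_identical(classify_pattern(make_trace_500(c(3, 9, 3.2)), 500), "C")
  # rising with a mid-course wobble still reads as overall increase
  expect_identical(
    classify_pattern(make_trace_500(c(2, 4, 3.5, 6, 8, 7.9)), 500), "A")
  expect_warning(
    lab <- classify_pattern(make_trace_500(c(5, 5, 5)), 500), "nearest")
  expect_true(lab %in% c("A", "B", "C"))
  expect_error(classify_pattern(make_trace_500(c(1, 2)), 500), "at least 3")
})

test_that("final/max percentage behaves, including the degenerate trace", {
  expect_equal(final_over_max(make_trace_500(c(2, 10, 7)), 500), 70)
  expect_equal(final_over_max(make_trace_500(1:6), 500), 100)
  expect_warning(v <- final_over_max(make_trace_500(rep(0, 3)), 500),
                 "undefined")
  expect_true(is.na(v))
})

test_that("two-frequency synchrony separates trauma from CF crossing", {
  n <- 40
  rise <- seq(2, 12, length.out = n)
  # synchronous step drop in both frequencies -> trauma
  both <- rise
  both[25:n] <- both[25:n] * 0.5
  tr_trauma <- make_trace(a250 = both, a500 = both)
  lab <- classify_drop_cause(tr_trauma)
  expect_identical(nrow(lab), 1L)
  expect_identical(lab$label, "trauma")
  # 500 drops while 250 keeps rising -> CF crossing
  fall500 <- c(seq(2, 12, length.out = 25), seq(11, 3, length.out = 15))
  tr_cf <- make_trace(a250 = rise, a500 = fall500)
  lab2 <- classify_drop_cause(tr_cf)
  expect_identical(nrow(lab2), 1L)
  expect_identical(lab2$label, "cf_crossing")
  # 500 drops, 250 declines mildly (sub-criterion) -> indeterminate
  drift250 <- seq(10, 8.5, length.out = n)
  lab3 <- classify_drop_cause(make_trace(a250 = drift250, a500 = fall500))
  expect_identical(lab3$label, "indeterminate")
  # flat traces: no events, no labels
  lab4 <- classify_drop_cause(make_trace(rep(5, n)))
  expect_identical(nrow(lab4), 0L)
  # single-frequency trace: indeterminate with warning
  expect_warning(lab5 <- classify_drop_cause(make_trace_500(fall500)),
                 "single-frequency")
  expect_true(all(lab5$label == "indeterminate"))
})

test_that("noiseless pipeline: scripted trauma labels as trauma and the
           trace equals the scripted excitation profile", {
  g <- cochlear_geometry(9.9, apical_angle_deg = 360)
  script <- event_script(data.frame(step_index = 30,
                                    attenuation_fraction = 0.5))
  sim <- simulate_insertion(g, script = script, noise_sd_uv = 0,
                            n_steps = 60)
  tr <- build_insertion_trace(sim)
  expect_equal(tr$amp_500, sim$truth$true_amplitude_uv[["500"]],
               tolerance = 1e-9)
  expect_equal(tr$amp_250, sim$truth$true_amplitude_uv[["250"]],
               tolerance = 1e-9)
  lab <- classify_drop_cause(tr)
  expect_true(nrow(lab) >= 1)
  expect_true(all(lab$label == "trauma"))
  expect_false(any(lab$label == "cf_crossing"))
})

test_that("noiseless small/deep cochlea labels its terminal 500-Hz decline
           as CF crossing", {
  g <- cochlear_geometry(8.4, apical_angle_deg = 430)
  sim <- simulate_insertion(g, noise_sd_uv = 0, n_steps = 60)
  expect_true(sim$truth$crossed_cf_500)
  tr <- build_insertion_trace(sim)
  lab <- classify_drop_cause(tr)
  expect_identical(nrow(lab), 1L)
  expect_identical(lab$label, "cf_crossing")
  # and the 250-Hz trace shows no drop events at all
  expect_identical(nrow(detect_drops(tr, 250)), 0L)
})

test_that("scripted attenuation is recovered through the full waveform
           pipeline on a locally flat excitation profile", {
  g <- cochlear_geometry(9.2, apical_angle_deg = 396)
  script <- event_script(data.frame(
    step_index = c(20, 32, 45),
    attenuation_fraction = c(0.6, 1 / 0.6, 0.5)))
  sim <- simulate_insertion(g, script = script, noise_sd_uv = 0,
                            n_steps = 60, excitation = flat_excitation())
  tr <- build_insertion_trace(sim)
  for (f in c(250, 500)) {
    ev <- detect_drops(tr, f)
    expect_identical(nrow(ev), 2L)
    expect_equal(ev$relative_drop, c(0.4, 0.5), tolerance = 1e-6)
  }
})

test_that("steps with non-finite samples are excluded with a warning", {
  g <- cochlear_geometry(9.2, apical_angle_deg = 396)
  sim <- simulate_insertion(g, noise_sd_uv = 0, n_steps = 12)
  sim$steps[[5]][["500"]]$cond$samples[10] <- NaN
  expect_warning(tr <- build_insertion_trace(sim), "non-finite")
  expect_identical(nrow(tr), 11L)
  expect_false(5L %in% tr$step)
})
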
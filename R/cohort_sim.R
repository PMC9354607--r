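# Cohort-level simulation: geometry, scripted trauma, analytic insertion
# traces, and audiograms tied to the 250-Hz drop through a linear model.

#' Default cohort-generator parameters
#'
#' Defaults emulate a perimodiolar implant cohort: cochlear diameter
#' 9.2 +/- 0.4 mm; apical insertion angle 396.5 +/- 40.2 degrees,
#' negatively correlated with diameter (r = -0.52, deeper insertions in
#' smaller cochleas); scripted trauma events at a Poisson rate with
#' multiplicative attenuations; per-case peak CM amplitude log-normal with
#' median 10 uV; and an LFPTA shift generated as
#' `intercept + slope_per_db * (true largest 250-Hz drop, dB) + residual`
#' with intercept 7.1 dB HL and slope 0.37 dB HL per dB of drop.
#'
#' @param electrode_type `"perimodiolar"` or `"lateral_wall"`; the latter
#'   switches to the shallower straight-array geometry distribution
#'   (294.1 +/- 41.9 degrees, diameter 9.4 +/- 0.6 mm, basal angle 0).
#' @return Named list of generator parameters.
#' @export
cohort_params <- function(electrode_type = c("perimodiolar", "lateral_wall")) {
  electrode_type <- match.arg(electrode_type)
  peri <- electrode_type == "perimodiolar"
  list(
    electrode_type = electrode_type,
    intercept_db = 7.1,
    slope_per_db = 0.37,
    resid_sd_db = 10,
    diameter_mean_mm = if (peri) 9.2 else 9.4,
    diameter_sd_mm = if (peri) 0.4 else 0.6,
    angle_mean_deg = if (peri) 396.5 else 294.1,
    angle_sd_deg = if (peri) 40.2 else 41.9,
    angle_diameter_r = -0.52,
    basal_angle_deg = if (peri) 20 else 0,
    event_rate = 1.5,
    atten_range = c(0.4, 0.9),
    peak_uv_meanlog = log(10),
    peak_uv_sdlog = 0.5,
    n_steps = 200L,
    pre_lfpta_mean = 50,
    pre_lfpta_sd = 8,
    threshold_jitter_sd = 3
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Analytic (noiseless, amplitude-level) insertion trace for one case.
analytic_trace <- function(geometry, excitation, script, n_steps) {
  angles <- seq(geometry$basal_angle_deg, geometry$apical_angle_deg,
                length.out = n_steps)
  mult <- script_multipliers(script, n_steps)
  amps <- lapply(c(250, 500), function(f) {
    excitation_amplitude(angles, cf_place_angle(f, geometry), excitation) *
      mult
  })
  names(amps) <- c("250", "500")
  insertion_trace(amps)
}

#' Simulate a cohort of implantations
#'
#' Generates `n_cases` cases: a cochlear geometry drawn from the electrode
#' type's distribution, scripted trauma events, a noiseless amplitude-level
#' insertion trace analysed with the standard trajectory metrics, and pre-
#' and postoperative audiograms whose LFPTA shift follows the linear model
#' `intercept + slope * (true largest 250-Hz drop) + Gaussian residual`.
#' Per-frequency thresholds scatter around the LFPTA with zero-sum jitter
#' so the case's `lfpta_shift` equals its generated shift exactly.
#'
#' @param n_cases Number of cases (>= 3).
#' @param params Parameter list from [cohort_params()] (fields may be
#'   overridden).
#' @param seed Integer seed for reproducibility.
#' @param waveforms If `TRUE`, each case also carries full waveform
#'   recordings from [simulate_insertion()] (slower; for pipeline
#'   end-to-end checks).
#' @return List of `case_record` objects; see [cohort_table()] for the flat
#'   per-case data frame.
#' @export
simulate_cohort <- function(n_cases, params = cohort_params(), seed = NULL,
                            waveforms = FALSE) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 3L) {
    stop("`n_cases` must be >= 3 for downstream statistics", call. = FALSE)
  }
  p <- params
  with_sim_seed(seed, {
    cases <- lapply(seq_len(n_cases), function(i) {
      d <- clamp(stats::rnorm(1, p$diameter_mean_mm, p$diameter_sd_mm),
                 8.05, 10.45)
      ang_mean <- p$angle_mean_deg + p$angle_diameter_r *
        (p$angle_sd_deg / p$diameter_sd_mm) * (d - p$diameter_mean_mm)
      ang_sd <- p$angle_sd_deg * sqrt(1 - p$angle_diameter_r^2)
      ang <- clamp(stats::rnorm(1, ang_mean, ang_sd),
                   p$basal_angle_deg + 120, 460)
      geom <- cochlear_geometry(d, apical_angle_deg = ang,
                                basal_angle_deg = p$basal_angle_deg)
      exc <- excitation_params(
        peak_uv = stats::rlnorm(1, p$peak_uv_meanlog, p$peak_uv_sdlog))

      n_ev <- stats::rpois(1, p$event_rate)
      script <- if (n_ev > 0) {
        event_script(data.frame(
          step_index = sample(2:p$n_steps, n_ev),
          attenuation_fraction = stats::runif(n_ev, p$atten_range[1],
                                              p$atten_range[2])))
      } else {
        event_script()
      }

      trace <- analytic_trace(geom, exc, script, p$n_steps)
      metrics <- suppressWarnings(insertion_metrics(trace))
      true_drop_250 <- largest_drop_db(trace, 250)

      shift <- p$intercept_db + p$slope_per_db * true_drop_250 +
        stats::rnorm(1, 0, p$resid_sd_db)
      base <- clamp(stats::rnorm(1, p$pre_lfpta_mean, p$pre_lfpta_sd), 5, 60)
      pre_jit <- stats::rnorm(3, 0, p$threshold_jitter_sd)
      pre_thr <- clamp(base + pre_jit - mean(pre_jit), -10, 130)
      post_jit <- stats::rnorm(3, 0, p$threshold_jitter_sd)
      post_thr <- clamp(pre_thr + shift + post_jit - mean(post_jit),
                        -10, 130)
      names(pre_thr) <- names(post_thr) <- c("125", "250", "500")
      pre <- audiogram(pre_thr)
      post <- audiogram(post_thr)

      rec <- NULL
      if (waveforms) {
        rec <- simulate_insertion(geom, script = script,
                                  n_steps = p$n_steps, excitation = exc)
      }

      structure(
        list(id = i, electrode_type = p$electrode_type, geometry = geom,
             excitation = exc, script = script, trace = trace,
             metrics = metrics, audiogram_pre = pre, audiogram_post = post,
             lfpta_shift = lfpta_shift(pre, post),
             truth = list(true_largest_drop_db_250 = true_drop_250,
                          nominal_shift_db = shift,
                          n_trauma_events = n_ev),
             recordings = rec),
        class = "case_record"
      )
    })
    cases
  })
}

#' Flatten a simulated cohort to a per-case table
#'
#' @param cases List of `case_record`s from [simulate_cohort()].
#' @return Data frame with one row per case: id, electrode type, geometry
#'   (diameter, apical angle), per-frequency trajectory metrics (drop
#'   count, largest drop dB, starting amplitude, final/max %, pattern), and
#'   pre/post LFPTA with the shift.
#' @export
cohort_table <- function(cases) {
  rows <- lapply(cases, function(cs) {
    m <- cs$metrics
    row <- data.frame(
      id = cs$id,
      electrode_type = cs$electrode_type,
      diameter_mm = cs$geometry$diameter_mm,
      apical_angle_deg = cs$geometry$apical_angle_deg,
      pre_lfpta = lfpta(cs$audiogram_pre),
      post_lfpta = lfpta(cs$audiogram_post),
      lfpta_shift = cs$lfpta_shift
    )
    for (f in c(250, 500)) {
      mr <- m[m$freq_hz == f, ]
      row[[paste0("n_drops_", f)]] <- mr$n_drops
      row[[paste0("largest_drop_db_", f)]] <- mr$largest_drop_db
      row[[paste0("start_amp_uv_", f)]] <- mr$start_amp_uv
      row[[paste0("final_over_max_pct_", f)]] <- mr$final_over_max_pct
      row[[paste0("pattern_", f)]] <- mr$pattern
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
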
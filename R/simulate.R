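# Synthetic multifrequency ECochG recordings: insertion runs and
# post-insertion electrode sweeps with scripted ground truth.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Sampled CM waveform for one epoch: amplitude * sinusoid at the stimulus
# frequency, gated by a linear-ramp burst envelope, polarity from phase.
synth_cm_samples <- function(amplitude_uv, stimulus, fs_hz, prestim_ms,
                             epoch_ms, phase_sign) {
  n <- round(epoch_ms * fs_hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs_hz
  rel <- t_ms - prestim_ms
  env <- rep(0, n)
  on <- rel >= 0 & rel <= stimulus$duration_ms
  r <- rel[on]
  env[on] <- pmin(1, r / stimulus$ramp_ms,
                  (stimulus$duration_ms - r) / stimulus$ramp_ms)
  phase_sign * amplitude_uv * env *
    sin(2 * pi * stimulus$freq_hz * rel / 1000)
}

# One condensation/rarefaction phase pair at a given CM amplitude.
synth_phase_pair <- function(amplitude_uv, stimulus, fs_hz, prestim_ms,
                             epoch_ms, noise_sd_uv) {
  base_c <- synth_cm_samples(amplitude_uv, stimulus, fs_hz, prestim_ms,
                             epoch_ms, +1)
  n <- length(base_c)
  noise_c <- if (noise_sd_uv > 0) stats::rnorm(n, 0, noise_sd_uv) else 0
  noise_r <- if (noise_sd_uv > 0) stats::rnorm(n, 0, noise_sd_uv) else 0
  stim_c <- stimulus; stim_c$phase <- "condensation"
  stim_r <- stimulus; stim_r$phase <- "rarefaction"
  list(
    cond = epoch_recording(base_c + noise_c, fs_hz, prestim_ms, stim_c),
    rare = epoch_recording(-base_c + noise_r, fs_hz, prestim_ms, stim_r)
  )
}

# Stimulus-free phase pairs used to estimate the analysis noise floor
# (the recorded analogue of clamping the sound tube).
synth_noise_pairs <- function(n_pairs, stimuli, fs_hz, prestim_ms, epoch_ms,
                              noise_sd_uv) {
  lapply(seq_len(n_pairs), function(i) {
    lapply(stimuli, function(st) {
      synth_phase_pair(0, st, fs_hz, prestim_ms, epoch_ms, noise_sd_uv)
    })
  })
}

#' Default per-sample recording noise (microvolts)
#'
#' Calibrated in closed form so that the single-sweep analysis noise floor
#' at 500 Hz is ~1 uV: the expected DFT-bin amplitude of white noise after
#' the halved difference curve is `(sd/sqrt(2)) * sqrt(pi/N)` with `N = 120`
#' window samples under the insertion defaults, giving `sd = sqrt(2*120/pi)`.
#'
#' @return Noise standard deviation in microvolts (~8.74).
#' @export
default_noise_sd <- function() {
  sqrt(2 * 120 / pi)
}

#' Simulate a multifrequency ECochG insertion run
#'
#' Advances the most-apical electrode linearly in angle from
#' `basal_angle_deg` to `apical_angle_deg` over `n_steps` presentations. At
#' each step both stimuli (250 and 500 Hz) are presented once per phase; the
#' recorded CM amplitude follows the tonotopic excitation profile around
#' each stimulus' CF place, scaled by any scripted trauma attenuations
#' (applied identically to both frequencies), with i.i.d. Gaussian sample
#' noise added per epoch. Stimulus-free phase pairs for noise-floor
#' estimation are appended.
#'
#' @param geometry A [cochlear_geometry()].
#' @param stimuli Named list of [tone_burst()] stimuli
#'   (default [protocol_stimuli()]`("insertion")`).
#' @param script An [event_script()] of scripted trauma events.
#' @param noise_sd_uv Per-sample Gaussian noise sd, microvolts
#'   (default [default_noise_sd()]; 0 for noiseless runs).
#' @param n_steps Number of insertion presentations (default 200).
#' @param seed Integer seed; identical seeds reproduce identical recordings.
#' @param excitation An [excitation_params()].
#' @param fs_hz,prestim_ms,epoch_ms Acquisition parameters (20 kHz, 1 ms,
#'   14 ms insertion epoch).
#' @param n_noise_pairs Stimulus-free phase pairs to append (default 20).
#' @return An object of class `insertion_simulation`: a list with `steps`
#'   (per step, per frequency, `cond`/`rare` [epoch_recording()]s),
#'   `noise_pairs`, `truth` (a `sim_truth` ground-truth log), `geometry`,
#'   `stimuli`, and the acquisition/config metadata.
#' @export
simulate_insertion <- function(geometry,
                               stimuli = protocol_stimuli("insertion"),
                               script = event_script(),
                               noise_sd_uv = default_noise_sd(),
                               n_steps = 200L, seed = NULL,
                               excitation = excitation_params(),
                               fs_hz = 20000, prestim_ms = 1, epoch_ms = 14,
                               n_noise_pairs = 20L) {
  stopifnot(inherits(geometry, "cochlear_geometry"),
            inherits(script, "event_script"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be >= 2", call. = FALSE)
  mult <- script_multipliers(script, n_steps)
  angles <- seq(geometry$basal_angle_deg, geometry$apical_angle_deg,
                length.out = n_steps)
  cf_angles <- vapply(stimuli, function(st) cf_place_angle(st$freq_hz, geometry),
                      numeric(1))
  true_amps <- lapply(seq_along(stimuli), function(j) {
    excitation_amplitude(angles, cf_angles[j], excitation) * mult
  })
  names(true_amps) <- names(stimuli)

  with_sim_seed(seed, {
    steps <- lapply(seq_len(n_steps), function(i) {
      pair <- lapply(seq_along(stimuli), function(j) {
        synth_phase_pair(true_amps[[j]][i], stimuli[[j]], fs_hz, prestim_ms,
                         epoch_ms, noise_sd_uv)
      })
      names(pair) <- names(stimuli)
      pair
    })
    noise_pairs <- synth_noise_pairs(n_noise_pairs, stimuli, fs_hz,
                                     prestim_ms, epoch_ms, noise_sd_uv)

    truth <- structure(
      list(
        cf_place_angle_deg = cf_angles,
        crossed_cf_500 = geometry$apical_angle_deg >
          cf_place_angle(500, geometry),
        crossed_cf_250 = geometry$apical_angle_deg >
          cf_place_angle(250, geometry),
        trauma_events = script$trauma_events,
        step_angles_deg = angles,
        true_amplitude_uv = true_amps,
        true_largest_drop_db = vapply(true_amps, largest_drop_db_vec,
                                      numeric(1))
      ),
      class = "sim_truth"
    )

    structure(
      list(kind = "insertion", steps = steps, noise_pairs = noise_pairs,
           truth = truth, geometry = geometry, stimuli = stimuli,
           fs_hz = fs_hz, prestim_ms = prestim_ms, epoch_ms = epoch_ms,
           noise_sd_uv = noise_sd_uv, seed = seed),
      class = "insertion_simulation"
    )
  })
}

#' Simulate a post-insertion electrode sweep
#'
#' Records from every even electrode (2, 4, ..., 22 on a 22-contact array)
#' after full insertion: `n_reps` condensation and `n_reps` rarefaction
#' epochs per stimulus, with the CM amplitude given by the excitation
#' profile at each contact's angular position.
#'
#' @inheritParams simulate_insertion
#' @param n_reps Repetitions per phase (default 30, the sweep protocol).
#' @param n_noise_sets Stimulus-free repetition sets appended for
#'   noise-floor estimation (default 12).
#' @param epoch_ms Sweep epoch duration (default 18 ms; 14-ms burst).
#' @return An object of class `sweep_simulation` with `electrodes` (named by
#'   electrode id; per frequency, lists of `cond` and `rare` epochs),
#'   `noise_sets`, `truth`, and metadata.
#' @export
simulate_sweep <- function(geometry, stimuli = protocol_stimuli("sweep"),
                           noise_sd_uv = default_noise_sd(), n_reps = 30L,
                           seed = NULL, excitation = excitation_params(),
                           fs_hz = 20000, prestim_ms = 1, epoch_ms = 18,
                           n_noise_sets = 12L) {
  stopifnot(inherits(geometry, "cochlear_geometry"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  ids <- seq(2L, geometry$n_electrodes, by = 2L)
  cf_angles <- vapply(stimuli, function(st) cf_place_angle(st$freq_hz, geometry),
                      numeric(1))

  with_sim_seed(seed, {
    electrodes <- lapply(ids, function(e) {
      ang <- geometry$electrode_angles_deg[e]
      per_freq <- lapply(seq_along(stimuli), function(j) {
        amp <- excitation_amplitude(ang, cf_angles[j], excitation)
        reps <- lapply(seq_len(n_reps), function(r) {
          synth_phase_pair(amp, stimuli[[j]], fs_hz, prestim_ms, epoch_ms,
                           noise_sd_uv)
        })
        list(cond = lapply(reps, `[[`, "cond"),
             rare = lapply(reps, `[[`, "rare"))
      })
      names(per_freq) <- names(stimuli)
      per_freq
    })
    names(electrodes) <- as.character(ids)

    noise_sets <- lapply(seq_len(n_noise_sets), function(i) {
      per_freq <- lapply(stimuli, function(st) {
        reps <- lapply(seq_len(n_reps), function(r) {
          synth_phase_pair(0, st, fs_hz, prestim_ms, epoch_ms, noise_sd_uv)
        })
        list(cond = lapply(reps, `[[`, "cond"),
             rare = lapply(reps, `[[`, "rare"))
      })
      per_freq
    })

    truth <- structure(
      list(
        cf_place_angle_deg = cf_angles,
        crossed_cf_500 = geometry$apical_angle_deg >
          cf_place_angle(500, geometry),
        crossed_cf_250 = geometry$apical_angle_deg >
          cf_place_angle(250, geometry),
        electrode_angles_deg = geometry$electrode_angles_deg[ids],
        true_amplitude_uv = lapply(seq_along(stimuli), function(j) {
          excitation_amplitude(geometry$electrode_angles_deg[ids],
                               cf_angles[j], excitation)
        })
      ),
      class = "sim_truth"
    )
    names(truth$true_amplitude_uv) <- names(stimuli)

    structure(
      list(kind = "sweep", electrodes = electrodes, noise_sets = noise_sets,
           truth = truth, geometry = geometry, stimuli = stimuli,
           fs_hz = fs_hz, prestim_ms = prestim_ms, epoch_ms = epoch_ms,
           n_reps = n_reps, noise_sd_uv = noise_sd_uv, seed = seed),
      class = "sweep_simulation"
    )
  })
}
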
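# Domain types for the synthetic cochlea: geometry, stimulus, event script.

#' Cochlear geometry for simulation
#'
#' Describes one implanted cochlea: its diameter (round-window centre through
#' the mid-modiolar axis to the lateral wall), the derived lateral-wall duct
#' length, and the angular positions of the electrode contacts after full
#' insertion. Electrode 1 is the most basal contact, electrode
#' `n_electrodes` (22 by default) the most apical; contact angles are spaced
#' linearly between `basal_angle_deg` and `apical_angle_deg`.
#'
#' @param diameter_mm Cochlear diameter in mm, within `[8.0, 10.5]`.
#' @param apical_angle_deg Angular insertion depth of the most-apical
#'   electrode (degrees).
#' @param basal_angle_deg Angular depth of the most-basal electrode
#'   (default 0).
#' @param n_electrodes Number of contacts on the array (default 22).
#' @return An object of class `cochlear_geometry` with fields
#'   `diameter_mm`, `duct_length_mm`, `apical_angle_deg`, `basal_angle_deg`,
#'   `n_electrodes`, and `electrode_angles_deg` (one angle per electrode,
#'   increasing from electrode 1 to electrode `n_electrodes`).
#' @examples
#' g <- cochlear_geometry(9.2, apical_angle_deg = 396)
#' g$duct_length_mm
#' @export
cochlear_geometry <- function(diameter_mm, apical_angle_deg,
                              basal_angle_deg = 0, n_electrodes = 22L) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L,
            is.numeric(apical_angle_deg), length(apical_angle_deg) == 1L,
            is.numeric(basal_angle_deg), length(basal_angle_deg) == 1L)
  if (diameter_mm < 8.0 || diameter_mm > 10.5) {
    stop("`diameter_mm` must lie in [8.0, 10.5] mm", call. = FALSE)
  }
  if (basal_angle_deg < 0 || apical_angle_deg <= basal_angle_deg) {
    stop("need apical_angle_deg > basal_angle_deg >= 0", call. = FALSE)
  }
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 2L) stop("need at least 2 electrodes", call. = FALSE)
  structure(
    list(
      diameter_mm = diameter_mm,
      duct_length_mm = duct_length_from_diameter(diameter_mm),
      apical_angle_deg = apical_angle_deg,
      basal_angle_deg = basal_angle_deg,
      n_electrodes = n_electrodes,
      electrode_angles_deg = seq(basal_angle_deg, apical_angle_deg,
                                 length.out = n_electrodes)
    ),
    class = "cochlear_geometry"
  )
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat(sprintf(
    "<cochlear_geometry> diameter %.2f mm, duct %.1f mm, %d electrodes, %0.f-%0.f deg\n",
    x$diameter_mm, x$duct_length_mm, x$n_electrodes,
    x$basal_angle_deg, x$apical_angle_deg))
  invisible(x)
}

#' Tone-burst stimulus descriptor
#'
#' @param freq_hz Stimulus frequency in Hz (the protocol uses 250 and 500).
#' @param duration_ms Burst duration in ms; must exceed `2 * ramp_ms`.
#' @param ramp_ms Linear onset/offset ramp time in ms.
#' @param level_db_spl Presentation level (dB SPL); carried as metadata.
#' @param phase `"condensation"` or `"rarefaction"` starting polarity.
#' @return An object of class `tone_burst`.
#' @export
tone_burst <- function(freq_hz, duration_ms = 10, ramp_ms = 1,
                       level_db_spl = NA_real_, phase = "condensation") {
  stopifnot(is.numeric(freq_hz), freq_hz > 0)
  if (duration_ms <= 2 * ramp_ms) {
    stop("`duration_ms` must exceed 2 * ramp_ms", call. = FALSE)
  }
  phase <- match.arg(phase, c("condensation", "rarefaction"))
  structure(
    list(freq_hz = freq_hz, duration_ms = duration_ms, ramp_ms = ramp_ms,
         level_db_spl = level_db_spl, phase = phase),
    class = "tone_burst"
  )
}

#' Default insertion-protocol stimuli
#'
#' The insertion protocol alternates 250- and 500-Hz tone bursts of 10 ms
#' duration with 1-ms ramps at 108 and 99.5 dB SPL respectively; the
#' post-insertion electrode sweep uses 14-ms bursts at the same levels.
#'
#' @param kind `"insertion"` (10-ms bursts) or `"sweep"` (14-ms bursts).
#' @return Named list of two `tone_burst` objects (`"250"`, `"500"`).
#' @export
protocol_stimuli <- function(kind = c("insertion", "sweep")) {
  kind <- match.arg(kind)
  dur <- if (kind == "insertion") 10 else 14
  list(
    "250" = tone_burst(250, duration_ms = dur, ramp_ms = 1,
                       level_db_spl = 108),
    "500" = tone_burst(500, duration_ms = dur, ramp_ms = 1,
                       level_db_spl = 99.5)
  )
}

#' Scripted simulation events (ground-truth trauma)
#'
#' Trauma is modelled as a persistent multiplicative attenuation applied
#' identically to both stimulus frequencies from a given insertion step
#' onward. `attenuation_fraction` is the retained fraction of the response
#' (0.5 halves the CM amplitude); values above 1 model later recovery/gain.
#'
#' @param trauma_events Data frame with columns `step_index` (integer) and
#'   `attenuation_fraction` (positive; in `(0, 1]` for attenuations), or
#'   `NULL` for an event-free insertion.
#' @return An object of class `event_script`.
#' @export
event_script <- function(trauma_events = NULL) {
  if (is.null(trauma_events)) {
    trauma_events <- data.frame(step_index = integer(0),
                                attenuation_fraction = numeric(0))
  }
  stopifnot(is.data.frame(trauma_events),
            all(c("step_index", "attenuation_fraction") %in%
                  names(trauma_events)))
  if (any(trauma_events$attenuation_fraction <= 0)) {
    stop("`attenuation_fraction` must be positive", call. = FALSE)
  }
  trauma_events$step_index <- as.integer(trauma_events$step_index)
  structure(list(trauma_events = trauma_events), class = "event_script")
}

# Cumulative attenuation multiplier per step for an n-step insertion.
script_multipliers <- function(script, n_steps) {
  ev <- script$trauma_events
  if (nrow(ev) > 0 &&
      (any(ev$step_index < 1L) || any(ev$step_index > n_steps))) {
    stop("event step indices must lie within the insertion (1..n_steps)",
         call. = FALSE)
  }
  mult <- rep(1, n_steps)
  for (i in seq_len(nrow(ev))) {
    k <- ev$step_index[i]
    mult[k:n_steps] <- mult[k:n_steps] * ev$attenuation_fraction[i]
  }
  mult
}
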
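# Post-insertion electrode-sweep analysis: per-electrode CM amplitudes,
# peak localization, CF-crossing determination, geometric risk rule.

#' Build an electrode sweep table from phase-set recordings
#'
#' For each recorded electrode, averages the repeated epochs within each
#' phase, forms the condensation-minus-rarefaction difference curve, and
#' extracts the cycle-aligned spectral amplitude per stimulus frequency.
#' Significance is judged against a noise floor estimated from
#' stimulus-free repetition sets processed identically (so the floor
#' reflects the same averaging).
#'
#' @param x A `sweep_simulation` (see [simulate_sweep()]) or a list with
#'   `electrodes`, `noise_sets`, `fs_hz`, `prestim_ms` in the same shape:
#'   `electrodes` is named by electrode id, and each entry maps frequency to
#'   lists `cond` and `rare` of [epoch_recording()]s.
#' @return Data frame of class `electrode_sweep` with columns `electrode`,
#'   `amp_<freq>`, `sig_<freq>`, plus a `noise_floor` attribute.
#' @export
sweep_from_recordings <- function(x) {
  electrodes <- x$electrodes
  if (length(electrodes) == 0L) stop("no electrode recordings", call. = FALSE)
  fs <- x$fs_hz
  prestim <- x$prestim_ms
  freqs <- names(electrodes[[1]])

  avg_epoch <- function(epochs) {
    m <- rowMeans(vapply(epochs, `[[`, numeric(length(epochs[[1]]$samples)),
                         "samples"))
    epoch_recording(m, epochs[[1]]$fs_hz, epochs[[1]]$prestim_ms,
                    epochs[[1]]$stimulus)
  }
  analyze_set <- function(set) {
    cond <- avg_epoch(set$cond)
    rare <- avg_epoch(set$rare)
    win <- ongoing_window(difference_curve(cond, rare), cond$stimulus, fs,
                          prestim)
    spectral_amplitude(win, fs, cond$stimulus$freq_hz)
  }

  floors <- lapply(freqs, function(f) {
    if (is.null(x$noise_sets) || length(x$noise_sets) < 5L) {
      return(list(mean_uv = 0, sd_uv = 0))
    }
    wins <- lapply(x$noise_sets, function(ns) {
      set <- ns[[f]]
      cond <- avg_epoch(set$cond)
      rare <- avg_epoch(set$rare)
      ongoing_window(difference_curve(cond, rare), cond$stimulus, fs, prestim)
    })
    estimate_noise_floor(wins, fs, as.numeric(f))
  })
  names(floors) <- freqs

  ids <- as.integer(names(electrodes))
  if (any(ids %% 2L != 0L)) {
    stop("electrode ids must be even (sweep records even contacts only)",
         call. = FALSE)
  }
  rows <- lapply(seq_along(electrodes), function(i) {
    entry <- electrodes[[i]]
    missing_phase <- vapply(entry, function(set) {
      length(set$cond) == 0L || length(set$rare) == 0L
    }, logical(1))
    if (any(missing_phase)) {
      message(sprintf("electrode %d missing a phase; entry skipped", ids[i]))
      return(NULL)
    }
    row <- data.frame(electrode = ids[i])
    for (f in freqs) {
      amp <- analyze_set(entry[[f]])
      row[[paste0("amp_", f)]] <- amp
      row[[paste0("sig_", f)]] <- is_significant(amp, floors[[f]])
    }
    row
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$electrode), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("electrode_sweep", "data.frame")
  attr(out, "noise_floor") <- floors
  out
}

#' Electrode with the maximum significant CM response
#'
#' @param sweep An `electrode_sweep` data frame.
#' @param freq Stimulus frequency (250 or 500).
#' @return Electrode id carrying the largest significant amplitude at
#'   `freq`; ties resolve to the more apical (higher-numbered) electrode.
#'   `NA` with a warning when no entry is significant.
#' @export
peak_electrode <- function(sweep, freq) {
  amp <- trace_col(sweep, freq)
  sig <- trace_col(sweep, freq, "sig")
  if (!any(sig)) {
    warning(sprintf("no significant %s-Hz responses in sweep", freq),
            call. = FALSE)
    return(NA_integer_)
  }
  amp[!sig] <- -Inf
  mx <- max(amp)
  candidates <- sweep$electrode[amp == mx]
  max(candidates)  # apical-most on ties
}

#' Did the apical electrode cross the CF place?
#'
#' Reads CF crossing off the electrode sweep: the most-apical contact has
#' passed the stimulus' CF place when the maximum CM response sits at an
#' electrode basal to it.
#'
#' @inheritParams peak_electrode
#' @param electrode_step Spacing of recorded contacts (2: even electrodes
#'   only), used to report how many recorded positions basal the peak sits.
#' @return List with `crossed` (flag), `peak_electrode`, `apical_electrode`,
#'   and `positions_basal` (recorded positions between peak and apical
#'   contact).
#' @export
crossed_cf <- function(sweep, freq, electrode_step = 2L) {
  pk <- peak_electrode(sweep, freq)
  apical <- max(sweep$electrode)
  if (is.na(pk)) {
    return(list(crossed = NA, peak_electrode = NA_integer_,
                apical_electrode = apical, positions_basal = NA_integer_))
  }
  list(
    crossed = pk < apical,
    peak_electrode = pk,
    apical_electrode = apical,
    positions_basal = as.integer((apical - pk) / electrode_step)
  )
}

#' Geometric CF-crossing risk rule
#'
#' An insertion is at risk of carrying the apical electrode past the 500-Hz
#' CF place when the cochlear diameter is below 9.5 mm and the apical
#' insertion angle exceeds 350 degrees (both strict).
#'
#' @param diameter_mm Cochlear diameter, mm.
#' @param apical_angle_deg Apical electrode insertion angle, degrees.
#' @param diameter_threshold_mm,angle_threshold_deg Rule thresholds
#'   (defaults 9.5 mm, 350 degrees).
#' @return List with `at_risk` flag, the two component flags, and a
#'   human-readable `rationale`.
#' @export
cf_crossing_risk <- function(diameter_mm, apical_angle_deg,
                             diameter_threshold_mm = 9.5,
                             angle_threshold_deg = 350) {
  stopifnot(diameter_mm > 0, apical_angle_deg > 0)
  small <- diameter_mm < diameter_threshold_mm
  deep <- apical_angle_deg > angle_threshold_deg
  list(
    at_risk = small && deep,
    small_cochlea = small,
    deep_insertion = deep,
    rationale = sprintf(
      "diameter %.1f mm %s %.1f mm and apical angle %.0f deg %s %.0f deg",
      diameter_mm, if (small) "<" else ">=", diameter_threshold_mm,
      apical_angle_deg, if (deep) ">" else "<=", angle_threshold_deg)
  )
}
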
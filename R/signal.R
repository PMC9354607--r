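# CM amplitude extraction from phase-pair epochs: difference curve,
# cycle-aligned ongoing-window FFT amplitude, noise floor, dB conversion.

#' Single-epoch recording
#'
#' One stimulus presentation's sampled waveform (microvolts) with its
#' acquisition parameters. The insertion protocol records 14-ms epochs
#' starting 1 ms before stimulus onset at 20 kHz.
#'
#' @param samples Numeric vector of samples in microvolts.
#' @param fs_hz Sampling rate in Hz (default 20000). Must exceed twice the
#'   stimulus frequency.
#' @param prestim_ms Pre-stimulus baseline duration in ms (default 1).
#' @param stimulus A [tone_burst()] describing the presented stimulus.
#' @return An object of class `epoch_recording`.
#' @export
epoch_recording <- function(samples, fs_hz = 20000, prestim_ms = 1,
                            stimulus = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "tone_burst"))
    if (fs_hz <= 2 * stimulus$freq_hz) {
      stop("sampling rate must exceed twice the stimulus frequency",
           call. = FALSE)
    }
  }
  structure(
    list(samples = as.numeric(samples), fs_hz = fs_hz,
         prestim_ms = prestim_ms, stimulus = stimulus),
    class = "epoch_recording"
  )
}

#' Condensation-minus-rarefaction difference curve
#'
#' Isolates the cochlear microphonic, which inverts with stimulus polarity,
#' by subtracting the rarefaction-phase response from the condensation-phase
#' response; phase-invariant components (summating potential, neural
#' responses, common-mode artefact) cancel. The difference is halved so the
#' result estimates the single-response CM amplitude.
#'
#' @param cond,rare `epoch_recording` objects for the two phases; must share
#'   length and sampling rate.
#' @return Numeric vector `(cond - rare) / 2` in microvolts.
#' @export
difference_curve <- function(cond, rare) {
  stopifnot(inherits(cond, "epoch_recording"),
            inherits(rare, "epoch_recording"))
  if (length(cond$samples) != length(rare$samples)) {
    stop("phase epochs differ in length", call. = FALSE)
  }
  if (cond$fs_hz != rare$fs_hz) {
    stop("phase epochs differ in sampling rate", call. = FALSE)
  }
  (cond$samples - rare$samples) / 2
}

#' Whole stimulus cycles contained in a time window
#'
#' @param freq_hz Stimulus frequency in Hz.
#' @param window_ms Window duration in ms.
#' @return Integer count of complete cycles, `floor(freq_hz * window_ms / 1000)`.
#' @examples
#' full_cycles(500, 8)   # 4
#' full_cycles(250, 12)  # 3
#' @export
full_cycles <- function(freq_hz, window_ms) {
  stopifnot(freq_hz > 0, window_ms >= 0)
  as.integer(floor(freq_hz * window_ms / 1000 + 1e-9))
}

#' Extract the ongoing portion of a difference curve
#'
#' Selects the steady-state ("ongoing") segment of the response for Fourier
#' analysis: from stimulus onset plus ramp plus a settling time, to the
#' start of the offset ramp, truncated to a whole number of stimulus cycles
#' so the FFT bin at the stimulus frequency is leakage-free.
#'
#' @param curve Numeric vector (a difference curve) covering the stimulus.
#' @param stimulus The [tone_burst()] that evoked it.
#' @param fs_hz Sampling rate in Hz.
#' @param prestim_ms Pre-stimulus baseline in the curve, ms.
#' @param settle_ms Post-ramp settling time excluded from the window
#'   (default 1 ms).
#' @return Numeric vector holding an integer number of stimulus cycles.
#'   With the insertion defaults (10-ms burst, 1-ms ramp) this retains 3
#'   cycles at 500 Hz and 1 cycle at 250 Hz.
#' @export
ongoing_window <- function(curve, stimulus, fs_hz = 20000, prestim_ms = 1,
                           settle_ms = 1) {
  stopifnot(is.numeric(curve), inherits(stimulus, "tone_burst"))
  start_ms <- prestim_ms + stimulus$ramp_ms + settle_ms
  end_ms <- prestim_ms + stimulus$duration_ms - stimulus$ramp_ms
  i_start <- round(start_ms * fs_hz / 1000) + 1L
  i_end <- round(end_ms * fs_hz / 1000)
  if (i_end > length(curve)) {
    stop("curve does not cover the stimulus duration", call. = FALSE)
  }
  avail_ms <- (i_end - i_start + 1L) * 1000 / fs_hz
  n_cyc <- full_cycles(stimulus$freq_hz, avail_ms)
  if (n_cyc < 1L) {
    stop("ongoing window shorter than one stimulus cycle", call. = FALSE)
  }
  n_keep <- round(n_cyc * fs_hz / stimulus$freq_hz)
  curve[i_start:(i_start + n_keep - 1L)]
}

#' Spectral amplitude at the stimulus frequency
#'
#' Discrete-Fourier magnitude at the bin nearest `f0_hz`, scaled to the peak
#' amplitude of the generating sinusoid (`2 * |X_k| / N`). On cycle-aligned
#' windows (see [ongoing_window()]) this is exact for pure tones.
#'
#' @param window Numeric vector (cycle-aligned for exact recovery).
#' @param fs_hz Sampling rate in Hz.
#' @param f0_hz Analysis frequency in Hz.
#' @return Amplitude in the units of `window` (microvolts here).
#' @export
spectral_amplitude <- function(window, fs_hz, f0_hz) {
  stopifnot(is.numeric(window))
  n <- length(window)
  if (n == 0L) stop("empty analysis window", call. = FALSE)
  if (n < fs_hz / f0_hz) {
    stop("window shorter than one cycle of `f0_hz`", call. = FALSE)
  }
  k <- round(f0_hz * n / fs_hz)
  x <- stats::fft(window)
  2 * Mod(x[k + 1L]) / n
}

#' Noise floor of the spectral-amplitude estimate
#'
#' Mean and standard deviation of [spectral_amplitude()] at `f0_hz` across
#' stimulus-free analysis windows (e.g. recorded with the sound tube
#' clamped, or pre-stimulus noise epochs passed through the same pipeline).
#'
#' @param noise_windows List of numeric vectors, each a stimulus-free
#'   analysis window; at least 5 are required.
#' @param fs_hz Sampling rate in Hz.
#' @param f0_hz Analysis frequency in Hz.
#' @return List with elements `mean_uv` and `sd_uv`.
#' @export
estimate_noise_floor <- function(noise_windows, fs_hz, f0_hz) {
  stopifnot(is.list(noise_windows))
  if (length(noise_windows) < 5L) {
    stop("need at least 5 noise windows to estimate the floor", call. = FALSE)
  }
  amps <- vapply(noise_windows, spectral_amplitude, numeric(1),
                 fs_hz = fs_hz, f0_hz = f0_hz)
  list(mean_uv = mean(amps), sd_uv = stats::sd(amps))
}

#' Response significance against the noise floor
#'
#' A response is significant when its spectral amplitude exceeds the noise
#' floor mean by more than 3 noise standard deviations.
#'
#' @param amplitude_uv Response amplitude(s), microvolts.
#' @param noise_floor List with `mean_uv` and `sd_uv` (see
#'   [estimate_noise_floor()]).
#' @param n_sd Criterion multiplier (default 3).
#' @return Logical vector.
#' @export
is_significant <- function(amplitude_uv, noise_floor, n_sd = 3) {
  amplitude_uv > noise_floor$mean_uv + n_sd * noise_floor$sd_uv
}

#' Amplitude in dB re 1 microvolt
#'
#' @param amplitude_uv Positive amplitude(s) in microvolts. Callers should
#'   clamp sub-noise-floor amplitudes to the noise mean before conversion.
#' @return `20 * log10(amplitude_uv)` in dB re 1 uV.
#' @examples
#' to_db(1)   # 0
#' to_db(10)  # 20
#' @export
to_db <- function(amplitude_uv) {
  if (any(!is.finite(amplitude_uv)) || any(amplitude_uv <= 0)) {
    stop("`amplitude_uv` must be positive and finite", call. = FALSE)
  }
  20 * log10(amplitude_uv)
}
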
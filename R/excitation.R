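# Tonotopic excitation profile: CM amplitude recorded at an electrode as a
# function of its angular distance from the CF place of the stimulus.

#' Excitation-profile parameters
#'
#' The recorded CM amplitude is modelled as an asymmetric two-sided
#' exponential in angular distance from the stimulus CF place: it grows as
#' the recording electrode approaches the CF place from the base, peaks
#' slightly basal of the place (outer-hair-cell drive summed over the basal
#' tail of the travelling wave), and collapses steeply once the electrode
#' passes apical of it.
#'
#' @param peak_uv Peak CM amplitude in microvolts.
#' @param basal_space_deg Exponential space constant on the basal (growth)
#'   side, degrees. The default (360) is the shallowest growth consistent
#'   with the apical-decay constraint below at the 3x asymmetry ratio; it
#'   keeps early-insertion amplitudes on the scale of reported starting CM
#'   amplitudes instead of burying them in the recording noise.
#' @param apical_space_deg Space constant on the apical (decay) side,
#'   degrees; steeper (smaller) than the basal one unless `symmetric`.
#' @param peak_offset_deg How far basal of the CF place the profile peaks,
#'   degrees.
#' @param symmetric If `TRUE`, the apical space constant is set equal to the
#'   basal one (no asymmetry).
#' @return An object of class `excitation_params`.
#' @export
excitation_params <- function(peak_uv = 10, basal_space_deg = 360,
                              apical_space_deg = 120, peak_offset_deg = 10,
                              symmetric = FALSE) {
  if (peak_uv <= 0 || basal_space_deg <= 0 || apical_space_deg <= 0) {
    stop("excitation scale parameters must be positive", call. = FALSE)
  }
  if (peak_offset_deg < 0) {
    stop("`peak_offset_deg` must be >= 0", call. = FALSE)
  }
  if (symmetric) apical_space_deg <- basal_space_deg
  structure(
    list(peak_uv = peak_uv, basal_space_deg = basal_space_deg,
         apical_space_deg = apical_space_deg,
         peak_offset_deg = peak_offset_deg, symmetric = symmetric),
    class = "excitation_params"
  )
}

#' CM excitation amplitude at an electrode position
#'
#' @param electrode_angle_deg Angular position(s) of the recording
#'   electrode, degrees.
#' @param cf_angle_deg Angular position of the stimulus CF place, degrees
#'   (see [cf_place_angle()]).
#' @param params An [excitation_params()] object.
#' @return CM amplitude(s) in microvolts; unimodal in `electrode_angle_deg`
#'   with the maximum `peak_offset_deg` basal of the CF place.
#' @export
excitation_amplitude <- function(electrode_angle_deg, cf_angle_deg,
                                 params = excitation_params()) {
  stopifnot(inherits(params, "excitation_params"))
  peak_angle <- cf_angle_deg - params$peak_offset_deg
  d <- electrode_angle_deg - peak_angle
  ifelse(d <= 0,
         params$peak_uv * exp(d / params$basal_space_deg),
         params$peak_uv * exp(-d / params$apical_space_deg))
}
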
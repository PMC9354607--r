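# Tonotopic map of the human cochlea: Greenwood frequency-position function
# plus the geometric conversions needed to express a characteristic-frequency
# (CF) place as an angular position along a specific cochlea.

# Human Greenwood constants (A in Hz; a per unit fractional distance; k
# dimensionless) and the reference organ-of-Corti duct length they were
# calibrated on.
.GREENWOOD_A <- 165.4
.GREENWOOD_a <- 2.1
.GREENWOOD_k <- 0.88
.REF_DUCT_MM <- 35.0

# Lateral-wall spiral constant set: arc length from the round window to
# angular depth theta is s(theta) = 2.62 * D * ln(1 + theta / 235) with D the
# cochlear diameter ("A value") in mm (Escude-type two-turn spiral fit).
.SPIRAL_C1 <- 2.62
.SPIRAL_C2 <- 235

#' Greenwood frequency-position function (human constants)
#'
#' Maps fractional distance along the cochlear duct, measured from the apex,
#' to characteristic frequency: `F = A * (10^(a*x) - k)` with the human
#' constants `A = 165.4` Hz, `a = 2.1`, `k = 0.88`.
#'
#' @param x_frac_from_apex Fractional distance from the apex, in `[0, 1]`
#'   (0 = apex, 1 = base).
#' @return Characteristic frequency in Hz. Strictly increasing in
#'   `x_frac_from_apex`.
#' @examples
#' greenwood_cf(0)      # apical limit, ~19.85 Hz
#' greenwood_cf(1)      # basal limit, ~20677 Hz
#' greenwood_position(500)  # ~0.282 of the duct up from the apex
#' @seealso [greenwood_position()] for the inverse, [cf_place_angle()] for
#'   the angular position on a specific cochlea.
#' @export
greenwood_cf <- function(x_frac_from_apex) {
  if (!is.numeric(x_frac_from_apex) || anyNA(x_frac_from_apex)) {
    stop("`x_frac_from_apex` must be numeric and non-missing", call. = FALSE)
  }
  if (any(x_frac_from_apex < 0 | x_frac_from_apex > 1)) {
    stop("`x_frac_from_apex` must lie in [0, 1]", call. = FALSE)
  }
  .GREENWOOD_A * (10^(.GREENWOOD_a * x_frac_from_apex) - .GREENWOOD_k)
}

#' Inverse Greenwood map: frequency to fractional place
#'
#' @param freq_hz Frequency in Hz; must lie within the invertible Greenwood
#'   range (about 19.85 Hz to 20.7 kHz for the human constants).
#' @return Fractional distance from the apex in `[0, 1]`.
#' @export
greenwood_position <- function(freq_hz) {
  if (!is.numeric(freq_hz) || anyNA(freq_hz)) {
    stop("`freq_hz` must be numeric and non-missing", call. = FALSE)
  }
  x <- log10(freq_hz / .GREENWOOD_A + .GREENWOOD_k) / .GREENWOOD_a
  if (any(x < 0 | x > 1)) {
    stop("`freq_hz` outside the invertible Greenwood range", call. = FALSE)
  }
  x
}

#' Cochlear duct length from cochlear diameter
#'
#' Affine regression of lateral-wall cochlear duct length (CDL, mm) on the
#' cochlear diameter measured from the round-window centre through the
#' mid-modiolar axis to the lateral wall: `CDL = 4.16 * diameter - 3.98`.
#'
#' @param diameter_mm Cochlear diameter in mm (> 0).
#' @return Duct length in mm, monotone increasing in the diameter.
#' @examples
#' duct_length_from_diameter(9.2)  # ~34.3 mm
#' @export
duct_length_from_diameter <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || anyNA(diameter_mm) || any(diameter_mm <= 0)) {
    stop("`diameter_mm` must be positive", call. = FALSE)
  }
  4.16 * diameter_mm - 3.98
}

# Arc length (mm) along the lateral wall from the round window to angular
# depth `angle_deg` for a cochlea of diameter `diameter_mm`.
spiral_arc_length <- function(angle_deg, diameter_mm) {
  if (any(angle_deg < 0)) stop("`angle_deg` must be >= 0", call. = FALSE)
  .SPIRAL_C1 * diameter_mm * log(1 + angle_deg / .SPIRAL_C2)
}

# Inverse of spiral_arc_length: angular depth (deg) at arc length `s_mm`.
spiral_angle_at_arc <- function(s_mm, diameter_mm) {
  if (any(s_mm < 0)) stop("arc length must be >= 0", call. = FALSE)
  .SPIRAL_C2 * (exp(s_mm / (.SPIRAL_C1 * diameter_mm)) - 1)
}

#' Angular position of a characteristic-frequency place
#'
#' Locates the CF place for a stimulus frequency on a specific cochlea and
#' expresses it as an angular insertion depth (degrees from the round
#' window). The CF place sits a fixed basilar-membrane distance from the
#' apex (the Greenwood fractional place times the 35-mm reference duct), so
#' in smaller cochleas the same frequency lies at a shorter distance -- and
#' hence a shallower angle -- from the base. The distance-from-base is
#' converted to an angle through the logarithmic lateral-wall spiral
#' `s(theta) = 2.62 * D * ln(1 + theta/235)`.
#'
#' @param freq_hz Stimulus frequency in Hz, within the Greenwood range and
#'   apical enough that its place lies inside this cochlea's duct.
#' @param geometry A [cochlear_geometry()] object (only `diameter_mm` and the
#'   derived `duct_length_mm` are used).
#' @return Angular position in degrees. For any geometry the 250-Hz place is
#'   apical of (larger angle than) the 500-Hz place.
#' @examples
#' g <- cochlear_geometry(diameter_mm = 9.2, apical_angle_deg = 396)
#' cf_place_angle(500, g)
#' cf_place_angle(250, g)  # more apical
#' @export
cf_place_angle <- function(freq_hz, geometry) {
  stopifnot(inherits(geometry, "cochlear_geometry"))
  x <- greenwood_position(freq_hz)       # fraction from apex
  dist_from_apex_mm <- x * .REF_DUCT_MM
  s_from_base <- geometry$duct_length_mm - dist_from_apex_mm
  if (any(s_from_base <= 0)) {
    stop("CF place for this frequency falls outside this cochlea's duct",
         call. = FALSE)
  }
  spiral_angle_at_arc(s_from_base, geometry$diameter_mm)
}
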
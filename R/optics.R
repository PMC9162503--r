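#' Optical configuration of an EFTL-equipped fluorescence microscope
#'
#' Bundles the constants of a wide-field fluorescence microscope whose focus
#' is swept by an electrically focus-tunable lens (EFTL) placed between the
#' objective and the sensor. The EFTL's optical power varies (approximately
#' linearly) with its drive current, which shifts the conjugate object plane
#' axially without moving any mechanical part.
#'
#' Defaults correspond to a 20x/0.5 NA water-immersion objective
#' (fMO = 9 mm, WD = 3.5 mm), an EFTL spanning 3 to -2 diopters over
#' 270 to -230 mA, EFTL-to-sensor distance 10 cm, objective-to-EFTL
#' distance 5 cm, and a 5.5 um sensor pixel pitch.
#'
#' @param fMO_mm Focal length of the microscope objective, in mm.
#' @param D_cm Distance from the EFTL to the sensor, in cm.
#' @param d_cm Distance from the objective back principal plane to the EFTL,
#'   in cm. Must be smaller than `D_cm`.
#' @param cal_currents_mA Two EFTL drive currents (mA) with known power.
#' @param cal_powers_dpt Optical powers (diopters) at those two currents.
#' @param numerical_aperture Objective numerical aperture (dimensionless).
#' @param WD_mm Objective working distance, in mm.
#' @param pixel_pitch_um Sensor pixel pitch, in micrometers.
#' @return An object of class `optics_config`.
#' @examples
#' cfg <- optics_config()
#' focusing_range(cfg)
#' @export
optics_config <- function(fMO_mm = 9, D_cm = 10, d_cm = 5,
                          cal_currents_mA = c(270, -230),
                          cal_powers_dpt = c(3, -2),
                          numerical_aperture = 0.5, WD_mm = 3.5,
                          pixel_pitch_um = 5.5) {
  if (!(fMO_mm > 0 && D_cm > 0 && d_cm > 0))
    stop_config("fMO_mm, D_cm and d_cm must all be positive")
  if (!(D_cm > d_cm))
    stop_config("the EFTL-to-sensor distance D must exceed the objective-to-EFTL distance d")
  if (length(cal_currents_mA) != 2L || length(cal_powers_dpt) != 2L)
    stop_config("power calibration needs exactly two (current, power) endpoint pairs")
  if (cal_currents_mA[1] == cal_currents_mA[2])
    stop_config("degenerate power calibration: the two calibration currents are equal")
  structure(list(
    fMO_mm = fMO_mm, D_cm = D_cm, d_cm = d_cm,
    cal_currents_mA = as.numeric(cal_currents_mA),
    cal_powers_dpt = as.numeric(cal_powers_dpt),
    numerical_aperture = numerical_aperture, WD_mm = WD_mm,
    pixel_pitch_um = pixel_pitch_um
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  objective: fMO = %g mm, NA = %g, WD = %g mm\n",
              x$fMO_mm, x$numerical_aperture, x$WD_mm))
  cat(sprintf("  geometry:  D = %g cm (EFTL-sensor), d = %g cm (objective-EFTL)\n",
              x$D_cm, x$d_cm))
  cat(sprintf("  EFTL cal:  %g dpt @ %g mA, %g dpt @ %g mA\n",
              x$cal_powers_dpt[1], x$cal_currents_mA[1],
              x$cal_powers_dpt[2], x$cal_currents_mA[2]))
  cat(sprintf("  sensor:    pixel pitch = %g um\n", x$pixel_pitch_um))
  invisible(x)
}

#' EFTL drive current to optical power
#'
#' Affine map through the two calibration endpoints of `cfg`. Currents
#' outside the calibrated interval are extrapolated with a warning.
#'
#' @param j_mA Drive current(s), in mA. Vectorized.
#' @param cfg An [optics_config()].
#' @return Optical power(s) in diopters.
#' @examples
#' current_to_power(270, optics_config())  # 3 diopters
#' @export
current_to_power <- function(j_mA, cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  jc <- cfg$cal_currents_mA
  pc <- cfg$cal_powers_dpt
  lo <- min(jc); hi <- max(jc)
  if (any(j_mA < lo | j_mA > hi))
    warning(sprintf(
      "current outside the calibrated range [%g, %g] mA; extrapolating", lo, hi))
  pc[1] + (j_mA - jc[1]) * (pc[2] - pc[1]) / (jc[2] - jc[1])
}

#' Equivalent focal power of objective + EFTL
#'
#' Two thin systems separated by d combine to the equivalent power
#' 1/feq = 1/fMO + P - P d / fMO. Affine in P; at P = 0 it reduces to
#' 1/fMO exactly.
#'
#' @param P EFTL optical power(s), diopters. Vectorized.
#' @inheritParams current_to_power
#' @return Equivalent focal power 1/feq, in 1/m.
#' @export
equivalent_power <- function(P, cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  fMO <- cfg$fMO_mm * 1e-3
  d <- cfg$d_cm * 1e-2
  1 / fMO + P - P * d / fMO
}

# Shared denominator of the focus-shift and magnification expressions:
# M(P) = 1/(P fMO) + (D - 1/P) / feq. The 1/P terms cancel algebraically
# (M is affine in P) but P = 0 is rejected as outside the model's domain.
mag_quotient <- function(P, cfg) {
  fMO <- cfg$fMO_mm * 1e-3
  D <- cfg$D_cm * 1e-2
  if (any(P == 0))
    stop_config("P = 0 is a singular configuration (1/P undefined); the corresponding drive current is outside the model's valid domain")
  1 / (P * fMO) + (D - 1 / P) * equivalent_power(P, cfg)
}

#' Axial focus shift of the conjugate plane
#'
#' Displacement z of the in-focus object plane from the objective's working
#' distance plane, as a function of EFTL power:
#' z = -fMO P (D - 1/P) / M(P), with M(P) the lateral magnification.
#'
#' @param P EFTL optical power(s), diopters; must be nonzero. Vectorized.
#' @inheritParams current_to_power
#' @return Focus shift(s) z in micrometers.
#' @export
focus_shift <- function(P, cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  fMO <- cfg$fMO_mm * 1e-3
  D <- cfg$D_cm * 1e-2
  M <- mag_quotient(P, cfg)
  if (any(abs(M) < 1e-12))
    stop_config("singular configuration: magnification denominator vanishes")
  z_m <- -fMO * P * (D - 1 / P) / M
  z_m * 1e6
}

#' Lateral magnification at the sensor
#'
#' M(P) = 1/(P fMO) + (D - 1/P)/feq. Varies with the EFTL power, which makes
#' the field of view current-dependent and motivates stack registration.
#'
#' @inheritParams focus_shift
#' @return Magnification(s), dimensionless.
#' @export
lateral_magnification <- function(P, cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  mag_quotient(P, cfg)
}

#' Lateral magnification at a given drive current
#'
#' Convenience composition [current_to_power()] then
#' [lateral_magnification()], used by model-based stack registration.
#'
#' @param j_mA Drive current(s), mA.
#' @inheritParams current_to_power
#' @return Magnification(s), dimensionless.
#' @export
magnification_at_current <- function(j_mA, cfg = optics_config()) {
  lateral_magnification(current_to_power(j_mA, cfg), cfg)
}

#' Axial focusing range of the system
#'
#' Evaluates the focus shift at the two calibrated power endpoints; the
#' range is the absolute difference. With the default configuration this is
#' about 210 micrometers.
#'
#' @inheritParams current_to_power
#' @return Named numeric vector `c(z_min, z_max, range)`, micrometers.
#' @export
focusing_range <- function(cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  z <- focus_shift(cfg$cal_powers_dpt, cfg)
  c(z_min = min(z), z_max = max(z), range = abs(z[2] - z[1]))
}

#' Maximum relative change of the lateral magnification
#'
#' 100 * (Mmax - Mmin) / Mmin over the calibrated power interval. M(P) is
#' affine in P, so the extrema sit at the endpoints; with the default
#' configuration the change is about 15 percent.
#'
#' @inheritParams current_to_power
#' @return Relative change in percent.
#' @export
relative_magnification_change <- function(cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  M <- lateral_magnification(cfg$cal_powers_dpt, cfg)
  100 * (max(M) - min(M)) / min(M)
}
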
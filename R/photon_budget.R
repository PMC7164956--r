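#' @title Photolysis photon budget
#' @description Scalar arithmetic linking laser pulse fluence to the expected
#'   number of absorbed photons per chromophore: photon energy h c / lambda,
#'   photon fluence, absorption cross-section from the molar extinction
#'   coefficient via sigma = ln(10) eps 1000 / N_A, and an attenuation factor
#'   for losses in the sample carrier (e.g. scattering in a grease jet).
#' @name photon_budget
NULL

PLANCK_H <- 6.626070e-34      # J s
SPEED_C <- 2.997925e8         # m/s
AVOGADRO <- 6.022141e23       # 1/mol

#' Photon energy
#'
#' @param wavelength Wavelength in nm, > 0.
#' @return Energy in joule (h c / lambda).
#' @export
photon_energy <- function(wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  PLANCK_H * SPEED_C / (wavelength * 1e-9)
}

#' Photon fluence of a pulse
#'
#' @param pulse_fluence Pulse energy density in mJ/mm^2, > 0.
#' @param wavelength Wavelength in nm, > 0.
#' @return Photons per mm^2.
#' @export
photon_fluence <- function(pulse_fluence, wavelength) {
  if (any(pulse_fluence <= 0)) stop("pulse_fluence must be > 0")
  (pulse_fluence * 1e-3) / photon_energy(wavelength)
}

#' Absorption cross-section from a molar extinction coefficient
#'
#' sigma = ln(10) eps 1000 / N_A in cm^2/molecule, returned in mm^2
#' (1 cm^2 = 100 mm^2).
#'
#' @param epsilon Molar (decadic) extinction coefficient in 1/(M cm), > 0.
#' @return Cross-section in mm^2 per molecule.
#' @export
cross_section <- function(epsilon) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0")
  (log(10) * epsilon * 1000 / AVOGADRO) * 100
}

#' Excitation specification
#'
#' @param wavelength nm, in (200, 1100).
#' @param pulse_fluence mJ/mm^2.
#' @param epsilon Molar extinction coefficient, 1/(M cm).
#' @param attenuation_factor Fluence reduction inside the carrier medium,
#'   >= 1 (1 = no attenuation). Supplied by the user, e.g. ~100 for strongly
#'   scattering grease jets.
#' @return List of class `excitation_spec`.
#' @export
excitation_spec <- function(wavelength, pulse_fluence, epsilon,
                            attenuation_factor = 1) {
  if (wavelength <= 200 || wavelength >= 1100) {
    stop("wavelength must lie in (200, 1100) nm")
  }
  if (pulse_fluence <= 0 || epsilon <= 0) stop("fluence and epsilon must be > 0")
  if (attenuation_factor < 1) stop("attenuation_factor must be >= 1")
  structure(list(wavelength = wavelength, pulse_fluence = pulse_fluence,
                 epsilon = epsilon, attenuation_factor = attenuation_factor),
            class = "excitation_spec")
}

#' Average photons absorbed per molecule
#'
#' photon_fluence x cross_section / attenuation_factor.
#'
#' @param spec An [excitation_spec()].
#' @return Dimensionless expected photon count per molecule.
#' @export
photons_per_molecule <- function(spec) {
  photon_fluence(spec$pulse_fluence, spec$wavelength) *
    cross_section(spec$epsilon) / spec$attenuation_factor
}

#' Full photon-budget table
#'
#' @param spec An [excitation_spec()].
#' @return data.frame with one labelled row per quantity in the chain.
#' @export
photon_budget <- function(spec) {
  e <- photon_energy(spec$wavelength)
  fl <- photon_fluence(spec$pulse_fluence, spec$wavelength)
  cs <- cross_section(spec$epsilon)
  data.frame(
    quantity = c("photon energy", "photon fluence", "cross-section",
                 "photons per molecule"),
    value = c(e, fl, cs, fl * cs / spec$attenuation_factor),
    units = c("J", "photons/mm^2", "mm^2/molecule", "-")
  )
}
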
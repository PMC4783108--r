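#' Concentration, number density and packing fraction conversions
#'
#' The experimental axis is a mass concentration c (mg/mL = g/L); the theory
#' works with the number density rho (nm^-3) and the packing fraction
#' phi = rho pi sigma0^3 / 6.  The mapping needs the protein molar mass;
#' the default 21 kDa is typical of a gamma-crystallin monomer.
#'
#' @param concentration mass concentration, mg/mL (>= 0).
#' @param density number density, nm^-3 (>= 0).
#' @param phi packing fraction in `[0, 1)`.
#' @param molar_mass protein molar mass, g/mol.
#' @param sigma0 crowder diameter, nm.
#' @return the converted quantity; all conversions are exact inverses of one
#'   another.
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
concentration_to_density <- function(concentration, molar_mass = 21000) {
  if (any(concentration < 0)) stop("`concentration` must be non-negative")
  if (molar_mass <= 0) stop("`molar_mass` must be positive")
  # (g/L) / (g/mol) * N_A molecules/mol / (1e24 nm^3/L)
  concentration / molar_mass * .AVOGADRO * 1e-24
}

#' @rdname unit_conversions
#' @export
density_to_concentration <- function(density, molar_mass = 21000) {
  if (any(density < 0)) stop("`density` must be non-negative")
  if (molar_mass <= 0) stop("`molar_mass` must be positive")
  density * molar_mass / .AVOGADRO * 1e24
}

#' @rdname unit_conversions
#' @export
density_to_packing <- function(density, sigma0 = 3.6) {
  if (any(density < 0)) stop("`density` must be non-negative")
  density * pi * sigma0^3 / 6
}

#' @rdname unit_conversions
#' @export
packing_to_density <- function(phi, sigma0 = 3.6) {
  .check_phi(phi)
  6 * phi / (pi * sigma0^3)
}

#' @rdname unit_conversions
#' @export
concentration_to_packing <- function(concentration, molar_mass = 21000,
                                     sigma0 = 3.6) {
  density_to_packing(concentration_to_density(concentration, molar_mass),
                     sigma0)
}

#' @rdname unit_conversions
#' @export
packing_to_concentration <- function(phi, molar_mass = 21000, sigma0 = 3.6) {
  density_to_concentration(packing_to_density(phi, sigma0), molar_mass)
}
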
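#' Define the crystallin association system
#'
#' Bundles every geometric and unit convention of the dimerization study:
#' spherical reactants of diameter `sigma` in a bath of spherical crowders
#' of diameter `sigma0` (identical crystallins by default), a
#' volume-conserving spherocylindrical product of asphericity `lambda`, and
#' the two transient complexes needed by the chemical binding model:
#'
#' * reactant-crowder complex: identified with the product species (both
#'   reactants and crowders are crystallins, so binding a crowder is
#'   indistinguishable from dimerization as far as the insertion work goes);
#' * product-crowder complex: a volume-conserving sphere holding the volume
#'   of the product plus one crowder, diameter \eqn{(2\sigma^3+\sigma_0^3)^{1/3}}
#'   (equal to \eqn{3^{1/3}\sigma} for identical crystallins).
#'
#' @param sigma reactant diameter, nm.
#' @param sigma0 crowder diameter, nm (sets the size ratio
#'   `sigma_ratio = sigma/sigma0`).
#' @param lambda product asphericity; 0 (spherical dimer) unless stated.
#' @param molar_mass monomer molar mass for concentration conversions, g/mol.
#' @param temperature absolute temperature, K.
#' @param product_sites rule for the number of binding sites carried by the
#'   product in the CBM: `"area"` (default) scales the reactant site count by
#'   the surface-area ratio, i.e. a fixed temperature-independent site
#'   density alpha; `"conserved"` gives the dimer `2 n_s - 2` sites (one site
#'   of each monomer consumed by the bond).
#' @return object of class `"crystallin_system"` carrying the four
#'   [species_geometry()] objects (`reactant`, `product`, `crowder`,
#'   `complex_rb`, `complex_pb`).
#' @examples
#' sys <- crystallin_system()
#' sys$reactant$coefficients   # A1 = 7, A2 = 7.5, A3 = 3
#' @export
crystallin_system <- function(sigma = 3.6, sigma0 = sigma, lambda = 0,
                              molar_mass = 21000, temperature = 298.15,
                              product_sites = c("area", "conserved")) {
  product_sites <- match.arg(product_sites)
  if (sigma <= 0 || sigma0 <= 0) stop("diameters must be positive")
  if (lambda < 0) stop("`lambda` must be non-negative")
  prod <- product_geometry(lambda, sigma, sigma0)
  pb_diam <- (2 * sigma^3 + sigma0^3)^(1 / 3)
  structure(list(
    sigma = sigma, sigma0 = sigma0, lambda = lambda,
    molar_mass = molar_mass, temperature = temperature,
    product_sites = product_sites,
    reactant   = reactant_geometry(sigma, sigma0),
    crowder    = reactant_geometry(sigma0, sigma0),
    product    = prod,
    complex_rb = prod,   # gamma_rb^st = gamma_p^st for identical crystallins
    complex_pb = species_geometry(pb_diam, lambda = 0, sigma0 = sigma0),
    v0 = pi * sigma0^3 / 6
  ), class = "crystallin_system")
}

#' @export
print.crystallin_system <- function(x, ...) {
  cat("<crystallin_system>\n")
  cat(sprintf("  reactant sigma = %.3f nm, crowder sigma0 = %.3f nm (ratio %.3f)\n",
              x$sigma, x$sigma0, x$sigma / x$sigma0))
  cat(sprintf("  product lambda = %.3f (cap %.4f nm, L %.4f nm)\n",
              x$lambda, x$product$cap_diameter, x$product$cylinder_length))
  cat(sprintf("  M = %g g/mol, T = %.2f K, product sites: %s\n",
              x$molar_mass, x$temperature, x$product_sites))
  invisible(x)
}

# packing fraction reached by a mass concentration under this system's units
.phi_of_c <- function(system, concentration) {
  concentration_to_packing(concentration, system$molar_mass, system$sigma0)
}
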
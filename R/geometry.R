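#' SPT shape coefficients of a hard spherocylindrical solute
#'
#' Coefficients of the scaled-particle-theory insertion-work polynomial for a
#' spherocylinder (hemispherical caps of diameter `sigma_ratio * sigma0`,
#' cylinder length `lambda` times the cap diameter) dissolved in a fluid of
#' hard spheres of diameter `sigma0`:
#' \deqn{A_1 = \varsigma^3 + 3\varsigma^2 + 3\varsigma +
#'       1.5\lambda(\varsigma^2 + 2\varsigma + 1)}
#' \deqn{A_2 = 3\varsigma^3 + 4.5\varsigma^2 + 4.5\lambda(\varsigma^2 + \varsigma)}
#' \deqn{A_3 = 3\varsigma^3 + 4.5\lambda\varsigma^2}
#' For a sphere the same size as the crowders (`sigma_ratio = 1`,
#' `lambda = 0`) this gives the classical (7, 7.5, 3).  In the point-solute
#' limit all three coefficients vanish and only the free-volume term
#' \eqn{-\ln(1-\phi)} of the insertion work survives.
#'
#' @param sigma_ratio ratio of the solute cap diameter to the crowder
#'   diameter (dimensionless, > 0).
#' @param lambda asphericity, cylinder length over cap diameter (>= 0).
#' @return named numeric vector `c(A1, A2, A3)`.
#' @export
shape_coefficients <- function(sigma_ratio, lambda = 0) {
  if (!is.numeric(sigma_ratio) || any(sigma_ratio <= 0))
    stop("`sigma_ratio` must be positive")
  if (!is.numeric(lambda) || any(lambda < 0))
    stop("`lambda` must be non-negative")
  s <- sigma_ratio
  c(A1 = s^3 + 3 * s^2 + 3 * s + 1.5 * lambda * (s^2 + 2 * s + 1),
    A2 = 3 * s^3 + 4.5 * s^2 + 4.5 * lambda * (s^2 + s),
    A3 = 3 * s^3 + 4.5 * lambda * s^2)
}

#' Hard-body geometry of one solute species
#'
#' A species is a spherocylinder: a cylinder of length `L = lambda *
#' cap_diameter` capped by two hemispheres of diameter `cap_diameter`
#' (a sphere when `lambda = 0`).  The constructor derives the size ratio
#' relative to the crowder diameter, the SPT shape coefficients, the volume
#' \eqn{\pi\sigma_p^3/6 + \pi\sigma_p^2 L/4} and the surface area
#' \eqn{\pi\sigma_p^2(1+\lambda)}.
#'
#' @param cap_diameter diameter of the hemispherical caps, nm.
#' @param lambda asphericity (>= 0); 0 gives a sphere.
#' @param sigma0 crowder diameter, nm.
#' @return an object of class `"species_geometry"`.
#' @seealso [product_geometry()], [reactant_geometry()]
#' @export
species_geometry <- function(cap_diameter, lambda = 0, sigma0) {
  if (!is.numeric(cap_diameter) || length(cap_diameter) != 1L ||
      cap_diameter <= 0)
    stop("`cap_diameter` must be a positive scalar")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a non-negative scalar")
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 <= 0)
    stop("`sigma0` must be a positive scalar")
  sp <- cap_diameter
  L <- lambda * sp
  structure(list(
    sigma_ratio     = sp / sigma0,
    lambda          = lambda,
    cap_diameter    = sp,
    cylinder_length = L,
    sigma0          = sigma0,
    coefficients    = shape_coefficients(sp / sigma0, lambda),
    volume          = pi * sp^3 / 6 + pi * sp^2 * L / 4,
    surface_area    = pi * sp^2 * (1 + lambda)
  ), class = "species_geometry")
}

#' @export
print.species_geometry <- function(x, ...) {
  shape <- if (x$lambda == 0) "sphere" else "spherocylinder"
  cat(sprintf("<species_geometry> %s\n", shape))
  cat(sprintf("  cap diameter %.4f nm, L = %.4f nm (lambda = %.3f)\n",
              x$cap_diameter, x$cylinder_length, x$lambda))
  cat(sprintf("  size ratio %.4f, volume %.4f nm^3, area %.4f nm^2\n",
              x$sigma_ratio, x$volume, x$surface_area))
  cat(sprintf("  A1 = %.4f, A2 = %.4f, A3 = %.4f\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  invisible(x)
}

#' Monomer (reactant) geometry
#'
#' A spherical crystallin of diameter `sigma` in a bath of crowders of
#' diameter `sigma0` (by default the crowders are the same crystallins,
#' `sigma0 = sigma`).
#'
#' @param sigma reactant diameter, nm.
#' @param sigma0 crowder diameter, nm.
#' @return `"species_geometry"` object.
#' @export
reactant_geometry <- function(sigma = 3.6, sigma0 = sigma) {
  species_geometry(sigma, lambda = 0, sigma0 = sigma0)
}

#' Volume-conserving dimer (product) geometry
#'
#' Two spherical reactants of diameter `sigma` associate into a
#' spherocylindrical product of asphericity `lambda`.  Conservation of the
#' combined volume \eqn{\pi\sigma^3/3} fixes the cap diameter,
#' \deqn{\sigma_p = \sigma\left(\frac{4}{3\lambda+2}\right)^{1/3},
#'       \qquad L = \lambda\,\sigma_p.}
#' For a spherical product (`lambda = 0`) this reduces to
#' \eqn{\sigma_p = 2^{1/3}\sigma}, `L = 0`.
#'
#' @param lambda product asphericity (>= 0).
#' @param sigma reactant diameter, nm.
#' @param sigma0 crowder diameter, nm.
#' @return `"species_geometry"` object.
#' @export
product_geometry <- function(lambda = 0, sigma = 3.6, sigma0 = sigma) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a non-negative scalar")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a positive scalar")
  sp <- sigma * (4 / (3 * lambda + 2))^(1 / 3)
  species_geometry(sp, lambda = lambda, sigma0 = sigma0)
}

#' Thermodynamic state of the crowded solution
#'
#' @param phi packing fraction of the crowders, in `[0, 1)`.  Values above
#'   0.4 trigger a warning: the SPT expressions neglect many-body effects
#'   and are reliable only at dilute and moderate packing.
#' @param temperature absolute temperature, K.
#' @param sigma0 crowder diameter, nm.
#' @return object of class `"solution_state"` with the number density
#'   `rho = 6 phi / (pi sigma0^3)` in nm^-3.  `phi` may be a vector.
#' @export
solution_state <- function(phi, temperature = 298.15, sigma0 = 3.6) {
  .check_phi(phi)
  if (any(phi > 0.4))
    warning("packing fraction above 0.4: SPT neglects many-body effects ",
            "and becomes unreliable at high packing", call. = FALSE)
  structure(list(
    phi = phi,
    rho = 6 * phi / (pi * sigma0^3),
    temperature = temperature,
    sigma0 = sigma0
  ), class = "solution_state")
}

.check_phi <- function(phi) {
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("`phi` must be finite numeric")
  if (any(phi < 0) || any(phi >= 1))
    stop("packing fraction must satisfy 0 <= phi < 1")
  invisible(phi)
}

#' Steric (hard-body) log activity coefficient
#'
#' SPT reversible work (in kT) of inserting the species into the hard-sphere
#' crowder fluid:
#' \deqn{\ln\gamma^{st} = -\ln(1-\phi) + A_1 x + A_2 x^2 + A_3 x^3,
#'       \qquad x = \phi/(1-\phi).}
#'
#' @param geom a [species_geometry()].
#' @param state a [solution_state()] (or a numeric vector of packing
#'   fractions).
#' @return numeric vector of log activity coefficients, one per `phi`.
#' @export
steric_log_activity <- function(geom, state) {
  phi <- if (inherits(state, "solution_state")) state$phi else state
  .check_phi(phi)
  .lng_steric(geom$coefficients, phi)
}

.lng_steric <- function(A, phi) {
  x <- phi / (1 - phi)
  -log1p(-phi) + A[[1]] * x + A[[2]] * x^2 + A[[3]] * x^3
}

# d ln(gamma^st) / d phi
.dlng_steric_dphi <- function(A, phi) {
  x <- phi / (1 - phi)
  1 / (1 - phi) + (A[[1]] + 2 * A[[2]] * x + 3 * A[[3]] * x^2) / (1 - phi)^2
}

#' Carnahan-Starling contact value of the radial distribution function
#'
#' \deqn{g_0^{max} = \frac{1-\phi/2}{(1-\phi)^3}}
#' equals 1 in the ideal-gas limit and grows monotonically with packing.
#'
#' @param phi packing fraction, in `[0, 1)`.
#' @return numeric vector.
#' @export
contact_value_g0max <- function(phi) {
  .check_phi(phi)
  (1 - phi / 2) / (1 - phi)^3
}

# d g0max / d phi
.dg0max_dphi <- function(phi) (2.5 - phi) / (1 - phi)^4
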
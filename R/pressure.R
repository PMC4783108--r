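# Osmotic pressure of the crystallin suspension from the density-dependent
# activity coefficient:
#
#   Pi = RT [ rho + Int_0^rho rho' (d ln gamma / d rho') d rho' ]
#
# with ln gamma the *monomer* (reactant) total log activity -- the measured
# suspension is of monomeric crystallins.  The integrand uses the analytic
# derivative assembled below; numeric differentiation is kept only as a test
# oracle.

# analytic d ln(gamma_total)/d phi for reactant or product
.dlng_total_dphi <- function(system, model, phi, species = "reactant") {
  geom <- system[[species]]
  dst <- .dlng_steric_dphi(geom$coefficients, phi)
  if (is.null(model)) return(dst)
  if (inherits(model, "tpm_model")) {
    rg <- .tpm_ranges(model, system$sigma)
    g0 <- contact_value_g0max(phi)
    rho <- phi / system$v0
    # d/dphi [ -rho eps S (dr + (g0-1) theta) ],  rho = phi/v0
    dst - model$epsilon * geom$surface_area *
      ((rg$delta_r + (g0 - 1) * rg$theta) / system$v0 +
         rho * rg$theta * .dg0max_dphi(phi))
  } else if (inherits(model, "cbm_model")) {
    complex <- if (species == "reactant") system$complex_rb
               else system$complex_pb
    Ax <- geom$coefficients; Ab <- system$crowder$coefficients
    Ac <- complex$coefficients
    D <- .lng_steric(Ax, phi) + .lng_steric(Ab, phi) - .lng_steric(Ac, phi)
    Dp <- .dlng_steric_dphi(Ax, phi) + .dlng_steric_dphi(Ab, phi) -
      .dlng_steric_dphi(Ac, phi)
    n <- .cbm_sites(system, model, species)
    q <- model$K * exp(D)
    dst - n * q * (1 + phi * Dp) / (1 + q * phi)
  } else stop("`model` must be NULL, a tpm_model or a cbm_model")
}

#' Osmotic pressure of the protein solution
#'
#' Integrates the density-dependent monomer activity coefficient,
#' \deqn{\Pi = RT\left[\rho + \int_0^{\rho}\rho'\,
#'   \frac{d\ln\gamma}{d\rho'}\,d\rho'\right],}
#' by adaptive quadrature of the analytic derivative.  With no attraction
#' (`model = NULL`) this is the SPT hard-sphere equation of state; with
#' `model = "ideal"` it is the van 't Hoff law \eqn{\Pi_i = \rho RT}.
#'
#' @param system a [crystallin_system()] (supplies molar mass, temperature
#'   and diameters for the concentration mapping).
#' @param model `NULL` (hard spheres), `"ideal"`, a [tpm_model()] or a
#'   [cbm_model()].
#' @param concentration protein mass concentration(s), mg/mL.  Alternatively
#'   give `density` (nm^-3) directly.
#' @param density number density(ies), nm^-3; overrides `concentration`.
#' @param rel_tol relative quadrature tolerance.
#' @return osmotic pressure(s) in kPa.
#' @export
osmotic_pressure <- function(system, model = NULL, concentration = NULL,
                             density = NULL, rel_tol = 1e-10) {
  rho <- if (!is.null(density)) density
         else if (!is.null(concentration))
           concentration_to_density(concentration, system$molar_mass)
         else stop("give `concentration` or `density`")
  if (any(rho < 0)) stop("density must be non-negative")
  phi_end <- rho * system$v0
  .check_phi(phi_end)
  if (any(phi_end > 0.4))
    warning("packing fraction above 0.4: SPT neglects many-body effects",
            call. = FALSE)
  fac <- .kpa_per_density(system$temperature)
  if (identical(model, "ideal")) return(fac * rho)
  v0 <- system$v0
  integrand <- function(r)
    r * v0 * .dlng_total_dphi(system, model, r * v0, "reactant")
  corr <- vapply(rho, function(r) {
    if (r == 0) return(0)
    stats::integrate(integrand, 0, r, rel.tol = rel_tol,
                     subdivisions = 200L)$value
  }, numeric(1))
  fac * (rho + corr)
}

#' Ideal (van 't Hoff) osmotic pressure
#'
#' \eqn{\Pi_i = \rho RT}, the reference law against which the attraction
#' models are compared.
#'
#' @param density number density, nm^-3 (>= 0).
#' @param temperature absolute temperature, K.
#' @return pressure in kPa.
#' @export
ideal_pressure <- function(density, temperature = 298.15) {
  if (any(density < 0)) stop("`density` must be non-negative")
  .kpa_per_density(temperature) * density
}

#' Osmotic-pressure isotherm container
#'
#' An ordered table of (concentration, pressure) pairs at fixed temperature;
#' the fitting target of the inference functions.
#'
#' @param concentration mg/mL, strictly increasing, non-negative.
#' @param pressure kPa, finite.
#' @param temperature K.
#' @return a data frame of class `"isotherm"` with columns `c_mg_per_mL`
#'   and `Pi_kPa` and a `temperature` attribute.
#' @export
isotherm <- function(concentration, pressure, temperature = 298.15) {
  if (length(concentration) != length(pressure))
    stop("`concentration` and `pressure` lengths differ")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(!is.finite(pressure))) stop("pressures must be finite")
  structure(data.frame(c_mg_per_mL = concentration, Pi_kPa = pressure),
            temperature = temperature,
            class = c("isotherm", "data.frame"))
}

#' Read / write an isotherm as CSV
#'
#' Plain CSV with mandatory header `c_mg_per_mL,Pi_kPa`; lines starting with
#' `#` are comments.  Values survive a round trip to 12 significant digits.
#'
#' @param path file path.
#' @param iso an [isotherm()].
#' @param temperature K, recorded in a comment on write and defaulted on
#'   read if no `# temperature_K:` comment is present.
#' @return `read_isotherm` returns an [isotherm()]; `write_isotherm`
#'   invisibly returns `path`.
#' @name isotherm_io
#' @export
read_isotherm <- function(path, temperature = 298.15) {
  lines <- readLines(path)
  tline <- grep("^#\\s*temperature_K:", lines, value = TRUE)
  if (length(tline))
    temperature <- as.numeric(sub("^#\\s*temperature_K:\\s*", "", tline[1]))
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data in ", path)
  body <- lines[keep]
  header <- strsplit(body[1], ",")[[1]]
  if (!identical(trimws(header), c("c_mg_per_mL", "Pi_kPa")))
    stop("malformed header in ", path,
         ": expected 'c_mg_per_mL,Pi_kPa', got '", body[1], "'")
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  bad <- which(diff(dat$c_mg_per_mL) <= 0)
  if (length(bad)) {
    lineno <- which(keep)[bad[1] + 2L]
    stop("concentrations not strictly increasing at line ", lineno,
         " of ", path)
  }
  isotherm(dat$c_mg_per_mL, dat$Pi_kPa, temperature)
}

#' @rdname isotherm_io
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# osmotic-pressure isotherm",
               sprintf("# temperature_K: %.6g", attr(iso, "temperature")),
               "c_mg_per_mL,Pi_kPa"), con)
  writeLines(sprintf("%.12g,%.12g", iso$c_mg_per_mL, iso$Pi_kPa), con)
  invisible(path)
}
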
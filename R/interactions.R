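#' Thermodynamic perturbation model (TPM) of intermolecular attraction
#'
#' Treats the orientationally averaged protein attraction of well depth
#' `epsilon` (in kT) acting over a range `delta_r` as a first-order
#' perturbation on the hard-sphere reference fluid.  The defaults follow the
#' calibration for globular proteins: `delta_r = 0.2 sigma` and decay range
#' `theta = (2^(1/6) - 1) sigma / 2` of the contact peak of the radial
#' distribution function, both resolved against the system's reactant
#' diameter when left `NULL`.
#'
#' @param epsilon orientationally averaged attraction depth, kT (>= 0).
#' @param delta_r attraction range, nm, or `NULL` for `0.2 sigma`.
#' @param theta decay range of the contact peak, nm, or `NULL` for
#'   `(2^(1/6)-1) sigma/2`.
#' @return object of class `"tpm_model"`.
#' @export
tpm_model <- function(epsilon, delta_r = NULL, theta = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a non-negative scalar (kT units)")
  structure(list(epsilon = epsilon, delta_r = delta_r, theta = theta),
            class = "tpm_model")
}

#' Chemical binding model (CBM) of intermolecular attraction
#'
#' Treats the attraction as reversible, nonspecific binding of crowders at
#' `n_sites` surface sites per reactant with a (temperature-dependent,
#' dimensionless) binding constant `K`.  The implied site density
#' `alpha = n_sites / S_reactant` is temperature independent; the product
#' species carries `alpha * S_product` sites under the default
#' area-proportional rule (see [crystallin_system()]).
#'
#' @param n_sites number of binding sites per reactant (>= 0).
#' @param K binding constant (>= 0).
#' @return object of class `"cbm_model"`.
#' @export
cbm_model <- function(n_sites, K) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 0)
    stop("`n_sites` must be a non-negative scalar")
  if (!is.numeric(K) || length(K) != 1L || K < 0)
    stop("`K` must be a non-negative scalar")
  structure(list(n_sites = n_sites, K = K), class = "cbm_model")
}

#' @export
print.tpm_model <- function(x, ...) {
  cat(sprintf("<tpm_model> epsilon = %.4g kT\n", x$epsilon)); invisible(x)
}

#' @export
print.cbm_model <- function(x, ...) {
  cat(sprintf("<cbm_model> n_sites = %g, K = %.4g\n", x$n_sites, x$K))
  invisible(x)
}

# resolve TPM ranges against the reference (reactant) diameter
.tpm_ranges <- function(model, sigma) {
  list(delta_r = if (is.null(model$delta_r)) 0.2 * sigma else model$delta_r,
       theta   = if (is.null(model$theta)) (2^(1 / 6) - 1) * sigma / 2
                 else model$theta)
}

#' Chemical log activity under the TPM
#'
#' \deqn{\ln\gamma^{ch} = -\rho\,\epsilon\,S\,[\delta r + (g_0^{max}-1)\theta]}
#' with \eqn{\rho} the crowder number density, `S` the surface area of the
#' inserted species and \eqn{g_0^{max}} the Carnahan-Starling contact value.
#' Always non-positive and exactly linear in `epsilon`.
#'
#' @param model a [tpm_model()].
#' @param geom the inserted species' [species_geometry()] (supplies `S`).
#' @param state a [solution_state()].
#' @param sigma reference diameter used for the default ranges, nm.
#' @return numeric vector, one value per `phi` in `state`.
#' @export
tpm_chem_log_activity <- function(model, geom, state, sigma = geom$sigma0) {
  rg <- .tpm_ranges(model, sigma)
  g0 <- contact_value_g0max(state$phi)
  -state$rho * model$epsilon * geom$surface_area *
    (rg$delta_r + (g0 - 1) * rg$theta)
}

#' Chemical log activity under the CBM
#'
#' Binding of crowders at `n_sites_species` equivalent surface sites:
#' \deqn{\ln\gamma^{ch} = -n_s \ln\!\left(1 + K\,
#'   \frac{\gamma^{st}_{x}\gamma^{st}_b}{\gamma^{st}_{x,b}}\,\phi\right)}
#' where the steric triplet holds the log activities of the inserted species
#' x, of a crowder b, and of the bound x-b complex.  Zero when `K = 0` or
#' `phi = 0`, and non-positive always.
#'
#' @param model a [cbm_model()] (supplies `K`).
#' @param n_sites_species site count of the inserted species.
#' @param state a [solution_state()].
#' @param steric_triplet numeric length-3 vector or 3-column matrix
#'   `(ln gamma_x^st, ln gamma_b^st, ln gamma_xb^st)`; rows follow `phi`.
#' @return numeric vector, one value per `phi`.
#' @export
cbm_chem_log_activity <- function(model, n_sites_species, state,
                                  steric_triplet) {
  if (n_sites_species < 0) stop("`n_sites_species` must be non-negative")
  st <- if (is.matrix(steric_triplet)) steric_triplet
        else matrix(steric_triplet, ncol = 3)
  excess <- st[, 1] + st[, 2] - st[, 3]
  -n_sites_species * log1p(model$K * exp(excess) * state$phi)
}

# site count of a species under the system's product-site rule
.cbm_sites <- function(system, model, species) {
  if (species == "reactant") return(model$n_sites)
  switch(system$product_sites,
    area      = model$n_sites * system$product$surface_area /
                system$reactant$surface_area,
    conserved = max(2 * model$n_sites - 2, 0))
}

# chemical log activity of reactant or product, dispatching on model class;
# model = NULL means pure hard spheres (no attraction).
.chem_log_activity <- function(system, model, phi, species) {
  if (is.null(model)) return(rep(0, length(phi)))
  state <- list(phi = phi, rho = phi / system$v0)
  geom <- system[[species]]
  if (inherits(model, "tpm_model")) {
    tpm_chem_log_activity(model, geom, state, sigma = system$sigma)
  } else if (inherits(model, "cbm_model")) {
    complex <- if (species == "reactant") system$complex_rb
               else system$complex_pb
    triplet <- cbind(.lng_steric(geom$coefficients, phi),
                     .lng_steric(system$crowder$coefficients, phi),
                     .lng_steric(complex$coefficients, phi))
    cbm_chem_log_activity(model, .cbm_sites(system, model, species),
                          state, triplet)
  } else stop("`model` must be NULL, a tpm_model or a cbm_model")
}

#' Total log activity coefficient of a species
#'
#' Sum of the steric SPT insertion work and the chemical (attractive)
#' contribution, \eqn{\ln\gamma = \ln\gamma^{st} + \ln\gamma^{ch}}.  With
#' `model = NULL` (or zero attraction) it reduces to the steric part alone.
#'
#' @param system a [crystallin_system()].
#' @param model `NULL` (hard spheres), a [tpm_model()] or a [cbm_model()].
#' @param phi packing fraction(s) in `[0, 1)`.
#' @param species `"reactant"` or `"product"`.
#' @return numeric vector of log activity coefficients.
#' @export
total_log_activity <- function(system, model, phi,
                               species = c("reactant", "product")) {
  species <- match.arg(species)
  .check_phi(phi)
  .lng_steric(system[[species]]$coefficients, phi) +
    .chem_log_activity(system, model, phi, species)
}

#' Crowding factor of the dimerization equilibrium
#'
#' The crowding (non-ideality) factor is the ratio of the association
#' constant in the crowded medium to its dilute-solution value,
#' \eqn{\Gamma = K/K_0 = \gamma_r^2/\gamma_p}, so
#' \eqn{\ln\Gamma = 2\ln\gamma_r - \ln\gamma_p}.  Positive values mean the
#' crowders push the equilibrium towards the dimer (depletion dominates),
#' negative values that attraction to the crowders stabilizes the monomers.
#'
#' @inheritParams total_log_activity
#' @return data frame with columns `phi`, `ln_gamma_r`, `ln_gamma_p`,
#'   `ln_Gamma`.
#' @export
crowding_factor <- function(system, model, phi) {
  .check_phi(phi)
  if (any(phi > 0.4))
    warning("packing fraction above 0.4: SPT neglects many-body effects",
            call. = FALSE)
  lr <- total_log_activity(system, model, phi, "reactant")
  lp <- total_log_activity(system, model, phi, "product")
  data.frame(phi = phi, ln_gamma_r = lr, ln_gamma_p = lp,
             ln_Gamma = 2 * lr - lp)
}

#' Binding constant equivalent to a TPM attraction depth
#'
#' Solves for the CBM binding constant `K` at which the chemical log
#' activity of the reactant matches the TPM value at the given packing
#' fraction: the two models then assign the same total activity coefficient
#' to the monomer.  The CBM expression is strictly monotone in `K`, so the
#' root is unique; at low density the map is linear in `epsilon`.
#'
#' @param system a [crystallin_system()].
#' @param epsilon TPM attraction depth, kT.
#' @param phi packing fraction (scalar, > 0).
#' @param n_sites CBM site count held fixed while solving.
#' @return list with `K`, the residual of the defining equation, and the
#'   matched `ln_gamma_ch`.
#' @export
equivalent_binding_constant <- function(system, epsilon, phi, n_sites = 2) {
  .check_phi(phi)
  if (length(phi) != 1L || phi <= 0) stop("`phi` must be a positive scalar")
  target <- .chem_log_activity(system, tpm_model(epsilon), phi, "reactant")
  if (target == 0) return(list(K = 0, residual = 0, ln_gamma_ch = 0))
  # -n_s log(1 + K q phi) = target  =>  closed-form bracket endpoint
  q <- exp(.lng_steric(system$reactant$coefficients, phi) +
           .lng_steric(system$crowder$coefficients, phi) -
           .lng_steric(system$complex_rb$coefficients, phi))
  f <- function(K) .chem_log_activity(system, cbm_model(n_sites, K), phi,
                                      "reactant") - target
  upper <- (exp(-target / n_sites) - 1) / (q * phi) * 2 + 1
  sol <- stats::uniroot(f, lower = 0, upper = upper, tol = 1e-14)
  list(K = sol$root, residual = f(sol$root), ln_gamma_ch = target)
}
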
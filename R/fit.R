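# Least-squares fits of the attraction parameters to osmotic-pressure
# isotherms, and the entropy-enthalpy compensation (crossover) solvers.
# All 1-D minimizations use bounded Brent search (stats::optimize); roots
# use Brent bracketing (stats::uniroot).  Loss: unweighted squared pressure
# residuals unless `weights` is given.

.fit_result <- function(parameters, rss, n_points, converged,
                        diagnostic = NULL, grid = NULL) {
  structure(list(parameters = parameters, residual_sum_of_squares = rss,
                 n_points = n_points, converged = converged,
                 diagnostic = diagnostic, parameter_grid = grid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  parameters:",
      paste(sprintf("%s = %.6g", names(x$parameters), x$parameters),
            collapse = ", "),
      sprintf("\n  RSS = %.6g over %d points (converged: %s)\n",
              x$residual_sum_of_squares, x$n_points, x$converged))
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n", sep = "")
  invisible(x)
}

.rss <- function(pred, obs, weights = NULL) {
  if (is.null(weights)) sum((pred - obs)^2)
  else sum(weights * (pred - obs)^2)
}

#' Fit the TPM attraction depth to an isotherm
#'
#' Minimizes the sum of squared pressure residuals over `epsilon >= 0`.
#' The TPM pressure is exactly linear in `epsilon`
#' (\eqn{\Pi(c;\epsilon) = \Pi_{hs}(c) - \epsilon D(c)}), so the two basis
#' curves are computed once and the 1-D minimization is cheap and convex.
#'
#' @param iso an [isotherm()] (at least 3 points).
#' @param system a [crystallin_system()].
#' @param epsilon_range search interval for `epsilon`, kT.
#' @param weights optional per-point weights for the squared residuals.
#' @return a `fit_result` with `parameters["epsilon"]`.
#' @export
fit_tpm_epsilon <- function(iso, system, epsilon_range = c(0, 30),
                            weights = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  if (nrow(iso) < 3) stop("need at least 3 isotherm points")
  cc <- iso$c_mg_per_mL
  pi_hs <- osmotic_pressure(system, NULL, concentration = cc)
  # basis slope: Pi(eps) = Pi_hs - eps * D  (exact linearity in eps)
  D <- pi_hs - osmotic_pressure(system, tpm_model(1), concentration = cc)
  obj <- function(e) .rss(pi_hs - e * D, iso$Pi_kPa, weights)
  opt <- stats::optimize(obj, epsilon_range, tol = 1e-9)
  eps <- opt$minimum
  on_edge <- min(eps - epsilon_range[1], epsilon_range[2] - eps) <
    1e-6 * diff(epsilon_range)
  .fit_result(c(epsilon = eps), opt$objective, nrow(iso),
              converged = !on_edge,
              diagnostic = if (on_edge)
                "minimum at search boundary; widen `epsilon_range`"
              else sprintf("interior Brent minimum in [%g, %g]",
                           epsilon_range[1], epsilon_range[2]))
}

#' Fit the CBM binding constant for each candidate site count
#'
#' Follows the grid-over-`n_sites` procedure: for every fixed `n_sites` the
#' binding constant `K` is determined by 1-D least squares, and the table of
#' `(n_sites, K, RSS)` makes the model-selection argument (which site count
#' describes the data best) reproducible as an RSS comparison.
#'
#' @param iso an [isotherm()].
#' @param system a [crystallin_system()].
#' @param n_sites_grid candidate site counts.
#' @param K_range search interval for `K`.
#' @param weights optional residual weights.
#' @return a `fit_result` for the best site count; its `parameter_grid`
#'   field holds the full `(n_sites, K, rss, converged)` table.
#' @export
fit_cbm <- function(iso, system, n_sites_grid = c(1, 2, 3, 10),
                    K_range = c(0, 1000), weights = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  if (nrow(iso) < 3) stop("need at least 3 isotherm points")
  if (!length(n_sites_grid)) stop("`n_sites_grid` must be non-empty")
  cc <- iso$c_mg_per_mL
  fit_one <- function(ns) {
    obj <- function(K) .rss(
      osmotic_pressure(system, cbm_model(ns, K), concentration = cc),
      iso$Pi_kPa, weights)
    opt <- stats::optimize(obj, K_range, tol = 1e-8)
    # refine on a narrow interval: Brent's attainable precision scales with
    # the interval, and recovery to 1e-6 relative needs the second pass
    lo <- max(K_range[1], opt$minimum / 2)
    hi <- min(K_range[2], opt$minimum * 2 + 1e-3)
    opt2 <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
    if (opt2$objective < opt$objective) opt <- opt2
    edge <- min(opt$minimum - K_range[1], K_range[2] - opt$minimum) <
      1e-6 * diff(K_range)
    c(K = opt$minimum, rss = opt$objective, converged = !edge)
  }
  tab <- t(vapply(n_sites_grid, fit_one, numeric(3)))
  grid <- data.frame(n_sites = n_sites_grid, K = tab[, "K"],
                     rss = tab[, "rss"],
                     converged = as.logical(tab[, "converged"]))
  best <- which.min(grid$rss)
  .fit_result(c(n_sites = grid$n_sites[best], K = grid$K[best]),
              grid$rss[best], nrow(iso),
              converged = grid$converged[best],
              diagnostic = if (!grid$converged[best])
                "K at search boundary for the best site count",
              grid = grid)
}

#' TPM attraction depth that mimics an ideal solute
#'
#' Least-squares matches the TPM pressure curve to the van 't Hoff law
#' \eqn{\rho RT} on a uniform concentration grid: the attraction depth at
#' which the steric pressure excess and the attractive pressure deficit
#' cancel over the stated range.
#'
#' @param system a [crystallin_system()].
#' @param c_range concentration interval (0 excluded from the grid), mg/mL.
#' @param n_grid number of uniform grid points.
#' @param epsilon_range search interval, kT.
#' @return a `fit_result` with `parameters["epsilon"]`.
#' @export
fit_ideal_epsilon <- function(system, c_range = c(0, 400), n_grid = 100,
                              epsilon_range = c(0, 30)) {
  if (diff(c_range) <= 0) stop("`c_range` must have positive width")
  cc <- seq(c_range[1] + diff(c_range) / n_grid, c_range[2],
            length.out = n_grid)
  target <- ideal_pressure(
    concentration_to_density(cc, system$molar_mass), system$temperature)
  iso <- isotherm(cc, target, system$temperature)
  fit <- fit_tpm_epsilon(iso, system, epsilon_range)
  fit$diagnostic <- sprintf(
    "matched to ideal law on %d uniform points over (%g, %g] mg/mL",
    n_grid, c_range[1], c_range[2])
  fit
}

#' Critical TPM attraction depth (entropy-enthalpy compensation)
#'
#' Solves \eqn{\ln\Gamma(\epsilon) = 0} at fixed packing fraction: the
#' attraction depth at which the depletion-driven promotion of dimerization
#' and its attraction-driven suppression cancel exactly.  Because
#' \eqn{\ln\Gamma} is linear in `epsilon`, the Brent root is unique whenever
#' the surface-area asymmetry \eqn{2S_r - S_p} is nonzero.
#'
#' @param system a [crystallin_system()].
#' @param phi packing fraction (scalar in (0, 1)).
#' @param epsilon_range bracketing interval for the root, kT.
#' @return list with `epsilon_c` and the residual `ln_Gamma` at the root.
#' @export
crossover_epsilon <- function(system, phi, epsilon_range = c(0, 100)) {
  .check_phi(phi)
  if (length(phi) != 1L || phi <= 0) stop("`phi` must be a positive scalar")
  dS <- 2 * system$reactant$surface_area - system$product$surface_area
  if (abs(dS) < 1e-10 * system$reactant$surface_area)
    stop("no crossover: the TPM chemical term cancels from ln Gamma when ",
         "2 S_reactant = S_product")
  f <- function(e) crowding_factor(system, tpm_model(e), phi)$ln_Gamma
  flo <- f(epsilon_range[1]); fhi <- f(epsilon_range[2])
  if (flo * fhi > 0)
    stop(sprintf(
      "no sign change of ln Gamma on [%g, %g]: ln Gamma = %.4g and %.4g",
      epsilon_range[1], epsilon_range[2], flo, fhi))
  sol <- stats::uniroot(f, epsilon_range, tol = 1e-12)
  list(epsilon_c = sol$root, residual = f(sol$root))
}

#' Compensation packing fraction for the CBM
#'
#' Brent root of \eqn{\ln\Gamma(\phi) = 0} for a chemical-binding model:
#' the packing fraction at which crowding stops affecting the association
#' equilibrium.  Errors informatively when \eqn{\ln\Gamma} does not change
#' sign on the bracket (e.g. for hard spheres, where it is positive for all
#' `phi > 0`).
#'
#' @param system a [crystallin_system()].
#' @param model a [cbm_model()] (a [tpm_model()] is accepted too).
#' @param bracket interval of packing fractions to search.
#' @return list with `phi_star` and the residual `ln_Gamma` at the root.
#' @export
crossover_phi_cbm <- function(system, model, bracket = c(0.01, 0.4)) {
  .check_phi(bracket)
  f <- function(p) crowding_factor(system, model, p)$ln_Gamma
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0)
    stop(sprintf(
      "ln Gamma does not change sign on [%g, %g]: ln Gamma = %.4g and %.4g",
      bracket[1], bracket[2], flo, fhi))
  sol <- stats::uniroot(f, bracket, tol = 1e-13)
  list(phi_star = sol$root, residual = f(sol$root))
}

#' Crowding-factor sweep tables
#'
#' Evaluates the activity coefficients and the crowding factor on a packing
#' fraction grid while one parameter sweeps a set of values, reproducing the
#' curve families of the analysis (asphericity, size ratio, attraction depth,
#' binding constant, site count).  Deterministic; rows ordered by
#' (value, phi).
#'
#' @param system base [crystallin_system()]; rebuilt per value for
#'   geometric parameters.
#' @param parameter one of `"lambda"`, `"sigma_ratio"`, `"epsilon"`, `"K"`,
#'   `"n_sites"`.
#' @param values grid of parameter values.
#' @param phi packing fraction grid.
#' @param model base attraction model: `NULL` for hard spheres (allowed for
#'   geometric sweeps), a [tpm_model()] for `"epsilon"`, a [cbm_model()]
#'   for `"K"`/`"n_sites"`; for geometric sweeps the model is held fixed.
#' @return long data frame: `parameter`, `value`, `phi`, `ln_gamma_r`,
#'   `ln_gamma_p`, `ln_Gamma`.
#' @export
sweep_crowding <- function(system, parameter, values,
                           phi = seq(0.01, 0.4, by = 0.01), model = NULL) {
  parameter <- match.arg(parameter,
                         c("lambda", "sigma_ratio", "epsilon", "K", "n_sites"))
  if (!length(values)) stop("`values` must be non-empty")
  one <- function(v) {
    sys_v <- system; mod_v <- model
    if (parameter == "lambda") {
      sys_v <- crystallin_system(system$sigma, system$sigma0, lambda = v,
                                 system$molar_mass, system$temperature,
                                 system$product_sites)
    } else if (parameter == "sigma_ratio") {
      sys_v <- crystallin_system(system$sigma, sigma0 = system$sigma / v,
                                 lambda = system$lambda, system$molar_mass,
                                 system$temperature, system$product_sites)
    } else if (parameter == "epsilon") {
      mod_v <- tpm_model(v, model$delta_r, model$theta)
    } else if (parameter == "K") {
      if (!inherits(model, "cbm_model")) stop("sweep over K needs a cbm_model")
      mod_v <- cbm_model(model$n_sites, v)
    } else if (parameter == "n_sites") {
      if (!inherits(model, "cbm_model"))
        stop("sweep over n_sites needs a cbm_model")
      mod_v <- cbm_model(v, model$K)
    }
    cbind(parameter = parameter, value = v,
          crowding_factor(sys_v, mod_v, phi))
  }
  out <- do.call(rbind, lapply(values, one))
  rownames(out) <- NULL
  out
}

#' Osmotic-pressure sweep table
#'
#' Pressure curves for a named list of models on a shared concentration
#' grid, with the ideal law included for reference.
#'
#' @param system a [crystallin_system()].
#' @param models named list; each element `NULL`, `"ideal"`, a
#'   [tpm_model()] or a [cbm_model()].
#' @param c_grid concentrations, mg/mL.
#' @return long data frame: `model`, `c_mg_per_mL`, `Pi_kPa`.
#' @export
sweep_pressure <- function(system, models, c_grid = seq(10, 400, by = 10)) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("`models` must be a fully named list")
  out <- lapply(names(models), function(nm)
    data.frame(model = nm, c_mg_per_mL = c_grid,
               Pi_kPa = osmotic_pressure(system, models[[nm]],
                                         concentration = c_grid)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
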
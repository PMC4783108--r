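#' Default concentration grid for synthetic isotherms
#'
#' Sixteen points spanning 25-400 mg/mL: the dilute limb plus the
#' physiological range of crystallin concentration in the lens
#' (200-400 mg/mL).
#'
#' @param n number of points.
#' @param range concentration range, mg/mL.
#' @return numeric vector, strictly increasing.
#' @export
default_c_grid <- function(n = 16, range = c(25, 400)) {
  seq(range[1], range[2], length.out = n)
}

#' Generate a synthetic osmotic-pressure isotherm
#'
#' Evaluates the chosen model's pressure curve on a concentration grid and
#' applies seeded multiplicative Gaussian noise,
#' \eqn{\Pi_i = \Pi_{model}(c_i)(1+\eta_i)}, \eqn{\eta_i \sim N(0, sd^2)} --
#' membrane-osmometry error scales with the signal.  With `noise_sd = 0` the
#' output is the exact model evaluation, the inverse fixture of the
#' parameter-recovery fits.
#'
#' @param system a [crystallin_system()].
#' @param model `NULL` (hard spheres), `"ideal"`, a [tpm_model()] or a
#'   [cbm_model()].
#' @param c_grid concentration grid, mg/mL, strictly increasing.
#' @param noise_sd relative standard deviation of the noise (>= 0).
#' @param noise_type multiplicative (default) or additive; additive noise is
#'   scaled by the mean model pressure.
#' @param seed integer seed; mandatory when `noise_sd > 0` so every
#'   realization is reproducible.
#' @return an [isotherm()].
#' @export
simulate_isotherm <- function(system, model, c_grid = default_c_grid(),
                              noise_sd = 0.05,
                              noise_type = c("multiplicative", "additive"),
                              seed = NULL) {
  noise_type <- match.arg(noise_type)
  if (any(diff(c_grid) <= 0)) stop("`c_grid` must be strictly increasing")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is mandatory when `noise_sd` > 0")
  pi_model <- osmotic_pressure(system, model, concentration = c_grid)
  if (noise_sd > 0) {
    set.seed(seed)
    eta <- stats::rnorm(length(c_grid), 0, noise_sd)
    pi_model <- switch(noise_type,
      multiplicative = pi_model * (1 + eta),
      additive       = pi_model + mean(pi_model) * eta)
  }
  isotherm(c_grid, pi_model, system$temperature)
}
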
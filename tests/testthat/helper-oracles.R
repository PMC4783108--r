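# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# central finite difference
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# spherocylinder volume from raw dimensions
spherocyl_volume <- function(cap, lambda) {
  pi * cap^3 / 6 + pi * cap^2 * (lambda * cap) / 4
}

# cap diameter of the volume-conserving dimer, by bisection on the volume
# equation rather than the closed form
solve_cap_bisection <- function(lambda, sigma, tol = 1e-14) {
  target <- pi * sigma^3 / 3
  lo <- 1e-9; hi <- 2 * sigma
  while (hi - lo > tol * sigma) {
    mid <- (lo + hi) / 2
    if (spherocyl_volume(mid, lambda) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# composite Simpson quadrature (fixed mesh), as an integration oracle
simpson <- function(f, a, b, n = 2000) {
  if (b == a) return(0)
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, by = 2)]) +
             2 * sum(y[seq(3, n - 1, by = 2)]))
}

# closed-form compensation attraction depth for the TPM:
# eps_c = (2 ln g_r^st - ln g_p^st) / (rho (2 S_r - S_p) [dr + (g0-1) theta])
closed_form_eps_c <- function(sys, phi) {
  lr <- steric_log_activity(sys$reactant, phi)
  lp <- steric_log_activity(sys$product, phi)
  rho <- 6 * phi / (pi * sys$sigma0^3)
  dr <- 0.2 * sys$sigma
  theta <- (2^(1 / 6) - 1) * sys$sigma / 2
  g0 <- (1 - phi / 2) / (1 - phi)^3
  dS <- 2 * sys$reactant$surface_area - sys$product$surface_area
  (2 * lr - lp) / (rho * dS * (dr + (g0 - 1) * theta))
}

# closed-form CBM binding constant matching a TPM chemical activity at
# fixed n_s:  -n_s ln(1 + K q phi) = lng_tpm  =>  K = (e^{-lng/n_s}-1)/(q phi)
closed_form_K_of_eps <- function(sys, eps, phi, n_sites = 2) {
  rho <- 6 * phi / (pi * sys$sigma0^3)
  dr <- 0.2 * sys$sigma
  theta <- (2^(1 / 6) - 1) * sys$sigma / 2
  g0 <- (1 - phi / 2) / (1 - phi)^3
  lng <- -rho * eps * sys$reactant$surface_area * (dr + (g0 - 1) * theta)
  q <- exp(steric_log_activity(sys$reactant, phi) +
             steric_log_activity(sys$crowder, phi) -
             steric_log_activity(sys$complex_rb, phi))
  (exp(-lng / n_sites) - 1) / (q * phi)
}

default_system <- function(...) crystallin_system(...)
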
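sys <- default_system()

test_that("noiseless isotherms return their generating parameters exactly", {
  iso_t <- simulate_isotherm(sys, tpm_model(13.9), noise_sd = 0)
  fit_t <- fit_tpm_epsilon(iso_t, sys)
  expect_true(fit_t$converged)
  expect_equal(fit_t$parameters[["epsilon"]], 13.9, tolerance = 1e-6)
  iso_c <- simulate_isotherm(sys, cbm_model(2, 10.6), noise_sd = 0)
  fit_c <- fit_cbm(iso_c, sys, n_sites_grid = 2, K_range = c(0, 100))
  expect_equal(fit_c$parameters[["K"]], 10.6, tolerance = 1e-6)
})

test_that("RSS over the site-count grid selects the generating n_sites", {
  iso <- simulate_isotherm(sys, cbm_model(2, 10.6), noise_sd = 0)
  fit <- fit_cbm(iso, sys, n_sites_grid = c(1, 2, 3, 10))
  grid <- fit$parameter_grid
  expect_equal(fit$parameters[["n_sites"]], 2)
  expect_true(all(grid$rss[grid$n_sites != 2] > grid$rss[grid$n_sites == 2]))
})

test_that("degenerate CBM fits are flagged, never silent", {
  iso <- simulate_isotherm(sys, cbm_model(2, 10.6), noise_sd = 0)
  # a 1-site model cannot reach the data; K runs into the search bound
  fit <- fit_cbm(iso, sys, n_sites_grid = 1, K_range = c(0, 50))
  expect_false(fit$converged)
  expect_gt(fit$residual_sum_of_squares, 0)
  expect_error(fit_cbm(iso, sys, n_sites_grid = numeric(0)), "non-empty")
  expect_error(fit_tpm_epsilon(isotherm(c(1, 2), c(1, 2)), sys), "3")
})

test_that("ideal-law data land on the ideal-matching attraction depth", {
  ref <- fit_ideal_epsilon(sys)
  cc <- default_c_grid(24, c(10, 400))
  iso <- isotherm(cc, ideal_pressure(concentration_to_density(cc)))
  fit <- fit_tpm_epsilon(iso, sys)
  expect_equal(fit$parameters[["epsilon"]], ref$parameters[["epsilon"]],
               tolerance = 0.1)
  expect_error(fit_ideal_epsilon(sys, c_range = c(100, 100)), "width")
  # halving the range shifts the matched depth only modestly
  half <- fit_ideal_epsilon(sys, c_range = c(0, 200))
  expect_false(half$parameters[["epsilon"]] == ref$parameters[["epsilon"]])
  expect_lt(abs(half$parameters[["epsilon"]] - ref$parameters[["epsilon"]]),
            2)
})

test_that("TPM crossover root matches the closed form on random draws", {
  set.seed(20160308)
  for (i in 1:50) {
    phi <- runif(1, 0.05, 0.38)
    lam <- runif(1, 0, 0.5)
    s0 <- 3.6 / runif(1, 0.6, 1.6)   # size ratio via crowder diameter
    sys_i <- crystallin_system(3.6, sigma0 = s0, lambda = lam)
    got <- crossover_epsilon(sys_i, phi, epsilon_range = c(0, 500))
    expect_equal(got$epsilon_c, closed_form_eps_c(sys_i, phi),
                 tolerance = 1e-10)
    expect_lt(abs(got$residual), 1e-10)
  }
})

test_that("crossover solver refuses a vanishing surface asymmetry", {
  # 2 S_r = S_p happens at the lambda solving (4/(3l+2))^(2/3) (1+l) = 2
  lam_deg <- uniroot(function(l) (4 / (3 * l + 2))^(2 / 3) * (1 + l) - 2,
                     c(2, 4), tol = 1e-12)$root
  sys_deg <- crystallin_system(lambda = lam_deg)
  expect_error(crossover_epsilon(sys_deg, 0.2), "no crossover")
})

test_that("CBM compensation root is tight and moves monotonically with K", {
  got <- crossover_phi_cbm(sys, cbm_model(2, 10.6))
  expect_lt(abs(got$residual), 1e-10)
  phis <- sapply(c(9.5, 10.6, 11.7), function(K)
    crossover_phi_cbm(sys, cbm_model(2, K))$phi_star)
  expect_true(all(diff(phis) > 0) || all(diff(phis) < 0))
  # hard spheres: ln Gamma > 0 everywhere, error path names the endpoints
  expect_error(crossover_phi_cbm(sys, cbm_model(2, 0)), "sign")
})

test_that("sweep tables are deterministic and reorder-invariant", {
  lam <- c(0, 0.2, 0.4)
  phi <- seq(0.05, 0.4, by = 0.05)
  tab <- sweep_crowding(sys, "lambda", lam, phi)
  tab_rev <- sweep_crowding(sys, "lambda", rev(lam), phi)
  reord <- tab_rev[order(tab_rev$value, tab_rev$phi), ]
  rownames(reord) <- NULL
  expect_equal(tab[order(tab$value, tab$phi), ], reord)
  # single-point grid equals direct crowding_factor calls
  one <- sweep_crowding(sys, "epsilon", 13.9, phi, model = tpm_model(1))
  expect_equal(one$ln_Gamma,
               crowding_factor(sys, tpm_model(13.9), phi)$ln_Gamma)
})

test_that("sweeps reproduce the attraction and shape orderings", {
  phi <- seq(0.05, 0.4, by = 0.05)
  lam_tab <- sweep_crowding(sys, "lambda", c(0, 0.1, 0.2, 0.3, 0.4), phi,
                            model = tpm_model(13.9))
  # at fixed phi, ln Gamma grows with product asphericity under the TPM
  for (p in phi) {
    cur <- lam_tab$ln_Gamma[lam_tab$phi == p]
    expect_true(all(diff(cur) > 0))
  }
  eps_tab <- sweep_crowding(sys, "epsilon", c(0, 5, 10, 15), phi,
                            model = tpm_model(1))
  for (p in phi) {
    cur <- eps_tab$ln_Gamma[eps_tab$phi == p]
    expect_true(all(diff(cur) < 0))
  }
  pr <- sweep_pressure(sys, list(ideal = "ideal", hs = NULL,
                                 tpm = tpm_model(13.9)),
                       c_grid = c(100, 300))
  expect_equal(nrow(pr), 6)
  expect_true(all(pr$Pi_kPa[pr$model == "tpm"] <
                    pr$Pi_kPa[pr$model == "ideal"]))
})

test_that("seeded 5% noise leaves parameter recovery essentially unbiased", {
  # Monte-Carlo recovery study; 200 replicates per model
  n_rep <- 200
  eps_hat <- K_hat <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    iso_t <- simulate_isotherm(sys, tpm_model(13.9), noise_sd = 0.05,
                               seed = 20160308 + i)
    eps_hat[i] <- fit_tpm_epsilon(iso_t, sys)$parameters[["epsilon"]]
    iso_c <- simulate_isotherm(sys, cbm_model(2, 10.6), noise_sd = 0.05,
                               seed = 50000 + i)
    K_hat[i] <- fit_cbm(iso_c, sys, n_sites_grid = 2,
                        K_range = c(0, 100))$parameters[["K"]]
  }
  expect_lt(abs(mean(eps_hat) - 13.9) / 13.9, 0.02)
  expect_lt(abs(mean(K_hat) - 10.6) / 10.6, 0.02)
  # and the generating value sits within two standard errors of the mean
  expect_lt(abs(mean(eps_hat) - 13.9), 2 * sd(eps_hat) / sqrt(n_rep))
})
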
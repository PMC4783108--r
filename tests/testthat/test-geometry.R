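test_that("volume-conserving product geometry matches the bisection oracle", {
  # spherical dimer: cap = 2^(1/3) sigma, L = 0
  g0 <- product_geometry(lambda = 0, sigma = 3.6)
  expect_equal(g0$cap_diameter, 2^(1 / 3) * 3.6, tolerance = 1e-12)
  expect_identical(g0$cylinder_length, 0)
  # unit diameter: product volume is pi/3 exactly
  expect_equal(product_geometry(0, sigma = 1)$volume, pi / 3,
               tolerance = 1e-12)
  # aspherical case against an independent bisection solve of the cubic
  g3 <- product_geometry(lambda = 0.3, sigma = 1)
  expect_equal(g3$cap_diameter, solve_cap_bisection(0.3, 1),
               tolerance = 1e-10)
  expect_equal(g3$cap_diameter, (4 / 2.9)^(1 / 3), tolerance = 1e-12)
  expect_equal(g3$cylinder_length, 0.3 * g3$cap_diameter)
})

test_that("product volume equals pi sigma^3 / 3 for any asphericity", {
  for (lam in seq(0, 1, by = 0.05)) {
    g <- product_geometry(lam, sigma = 3.6)
    expect_equal(spherocyl_volume(g$cap_diameter, lam), pi * 3.6^3 / 3,
                 tolerance = 1e-10)
  }
})

test_that("shape coefficients reproduce the printed sphere values", {
  expect_equal(shape_coefficients(1, 0),
               c(A1 = 7, A2 = 7.5, A3 = 3))
  # independent term-by-term evaluation for the spherical dimer
  s <- 2^(1 / 3)
  expect_equal(shape_coefficients(s, 0),
               c(A1 = (1 + s)^3 - 1, A2 = 3 * s^3 + 4.5 * s^2,
                 A3 = 3 * s^3),
               tolerance = 1e-12)
})

test_that("point-solute limit keeps only the free-volume insertion work", {
  A <- shape_coefficients(1e-12, 0)
  expect_true(all(abs(A) < 1e-8))
  g <- species_geometry(1e-9, 0, sigma0 = 3.6)
  expect_equal(steric_log_activity(g, 0.3), -log(1 - 0.3),
               tolerance = 1e-8)
})

test_that("sphere coefficients split the binomial (1+s)^3 - 1 across orders", {
  # at lambda = 0 the coefficients carry the pure-sphere insertion work;
  # checked against independent binomial identities for random size ratios
  set.seed(42)
  for (s in runif(20, 0.1, 3)) {
    A <- shape_coefficients(s, 0)
    expect_equal(unname(A[1]), (1 + s)^3 - 1, tolerance = 1e-12)
    expect_equal(unname(A[2] - A[3]), 4.5 * s^2, tolerance = 1e-12)
    expect_equal(unname(A[3]), 3 * s^3, tolerance = 1e-12)
  }
})

test_that("steric log activity matches hand sums and vanishes at phi = 0", {
  sys <- default_system()
  expect_identical(steric_log_activity(sys$reactant, 0), 0)
  # hand-sum oracle: -ln 0.8 + 7(0.25) + 7.5(0.25^2) + 3(0.25^3)
  expect_equal(steric_log_activity(sys$reactant, 0.2),
               -log(0.8) + 7 * 0.25 + 7.5 * 0.25^2 + 3 * 0.25^3,
               tolerance = 1e-12)
  # same oracle with the dimer's coefficients (Eq-6 values, lambda = 0)
  A <- shape_coefficients(2^(1 / 3), 0)
  expect_equal(steric_log_activity(sys$product, 0.2),
               -log(0.8) + A[[1]] * 0.25 + A[[2]] * 0.25^2 + A[[3]] * 0.25^3,
               tolerance = 1e-12)
  expect_equal(steric_log_activity(sys$product, 0.2), 3.7738417,
               tolerance = 1e-7)
})

test_that("steric log activity is monotone in phi, size ratio and lambda", {
  phi <- seq(0.01, 0.45, by = 0.02)
  sys <- default_system()
  expect_true(all(diff(steric_log_activity(sys$reactant, phi)) > 0))
  for (p in c(0.1, 0.25, 0.4)) {
    by_s <- sapply(seq(0.2, 2, by = 0.2), function(s)
      steric_log_activity(species_geometry(s * 3.6, 0, 3.6), p))
    expect_true(all(diff(by_s) > 0))
    by_l <- sapply(seq(0, 1, by = 0.1), function(l)
      steric_log_activity(species_geometry(3.6, l, 3.6), p))
    expect_true(all(diff(by_l) > 0))
  }
})

test_that("low-density slope of the insertion work is 1 + A1", {
  for (geom in list(reactant_geometry(), product_geometry(0.3))) {
    slope <- num_deriv(function(p) steric_log_activity(geom, p), 1e-7,
                       h = 1e-8)
    expect_equal(slope, 1 + geom$coefficients[["A1"]], tolerance = 1e-4)
  }
})

test_that("contact value follows the Carnahan-Starling form", {
  expect_identical(contact_value_g0max(0), 1)
  expect_equal(contact_value_g0max(0.2), 0.9 / 0.512, tolerance = 1e-12)
  expect_equal(contact_value_g0max(0.4), 0.8 / 0.216, tolerance = 1e-12)
  phi <- seq(0, 0.9, by = 0.05)
  expect_true(all(diff(contact_value_g0max(phi)) > 0))
})

test_that("concentration conversions round-trip and match hand values", {
  expect_identical(concentration_to_density(0), 0)
  expect_equal(concentration_to_packing(400, 21000, 3.6), 0.2802191,
               tolerance = 1e-6)
  expect_equal(packing_to_density(0.2, 3.6), 6 * 0.2 / (pi * 3.6^3),
               tolerance = 1e-12)
  expect_equal(packing_to_density(0.2, 3.6), 8.19e-3, tolerance = 1e-3)
  c0 <- c(1, 50, 400)
  expect_equal(density_to_concentration(concentration_to_density(c0)), c0,
               tolerance = 1e-12)
  expect_equal(packing_to_concentration(concentration_to_packing(c0)), c0,
               tolerance = 1e-12)
})

test_that("geometry and state constructors reject invalid domains", {
  expect_error(product_geometry(-0.1), "non-negative")
  expect_error(product_geometry(0, sigma = -1), "positive")
  expect_error(shape_coefficients(0), "positive")
  expect_error(shape_coefficients(1, -1), "non-negative")
  expect_error(solution_state(1), "phi < 1")
  expect_error(solution_state(-0.1), "phi")
  expect_error(steric_log_activity(reactant_geometry(), 1.2), "phi")
  expect_error(contact_value_g0max(1), "phi")
  expect_error(concentration_to_density(-5), "non-negative")
  expect_warning(solution_state(0.45), "many-body")
})
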
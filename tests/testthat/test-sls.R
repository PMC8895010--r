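test_that("optical constant matches direct evaluation and its scaling laws", {
  # frozen independent hand evaluation of 4 pi^2 n^2 (dn/dc)^2 / (N_A lambda^4)
  # at n = 1.325, dn/dc = 0.275 ml/g, lambda = 633 nm (in m)
  expect_equal(optical_constant(1.325, 0.275, 633e-9), 54.2114643434,
               tolerance = 1e-10)
  K <- optical_constant(1.4, 0.2, 500e-9)
  expect_equal(optical_constant(1.4, 0.4, 500e-9), 4 * K)
  expect_equal(optical_constant(1.4, 0.2, 250e-9), 16 * K)
  expect_error(optical_constant(-1, 0.2, 500e-9), "positive")
})

test_that("constant Debye series recovers the ideal-solution limit", {
  s <- concentration_series(seq(10, 90, length.out = 8), rep(1e-5, 8),
                            unit = "mg_per_ml", temperature = 298.15)
  f <- fit_virial(s)
  expect_equal(f$Mw_app, 1e5, tolerance = 1e-10)
  expect_equal(f$A2, 0, tolerance = 1e-12)
  expect_equal(f$A3, 0)
})

test_that("noiseless generated Debye data round-trip through the fit", {
  cfg <- generator_config(seed = 3, noise_sls = 0)
  f <- fit_virial(gen_sls(cfg))
  expect_equal(f$Mw_app, 2e4, tolerance = 1e-3 * 1e-1)   # <0.1% relative
  expect_equal(f$A2, 3e-4, tolerance = 3e-4 * 1e-3)
  # explicit cubic truth, explicit order-3 fit
  cfg3 <- generator_config(seed = 3, noise_sls = 0,
                           sls = list(Mw = 5e4, A2 = 2e-4, A3 = 5e-4))
  f3 <- fit_virial(gen_sls(cfg3), order = 3)
  expect_equal(f3$Mw_app, 5e4, tolerance = 5e4 * 1e-6)
  expect_equal(f3$A3, 5e-4, tolerance = 5e-4 * 1e-6)
  expect_true(isSymmetric(f3$covariance))
  expect_true(all(eigen(f3$covariance, only.values = TRUE)$values > -1e-20))
})

test_that("noisy fits sit within three standard errors of the truth", {
  cfg <- generator_config(seed = 11)
  f <- fit_virial(gen_sls(cfg))
  expect_lt(abs(f$Mw_app - 2e4), 3 * f$se[["Mw_app"]])
  expect_lt(abs(f$A2 - 3e-4), 3 * f$se[["A2"]])
})

test_that("Mw recovery is tight in the median over 200 noisy replicates", {
  errs <- vapply(1:200, function(i) {
    f <- fit_virial(gen_sls(generator_config(seed = 1000 + i)))
    abs(f$Mw_app - 2e4) / 2e4
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("underdetermined or invalid virial fits are refused", {
  s <- concentration_series(c(10, 20, 30), c(1e-5, 1.1e-5, 1.2e-5),
                            unit = "mg_per_ml")
  expect_error(fit_virial(s), "underdetermined")
  sM <- concentration_series(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(1e-5, 5),
                             unit = "M")
  expect_error(fit_virial(sM), "mass concentration")
})

test_that("osmotic pressure derivative follows the Debye ratio", {
  cfg <- generator_config(seed = 3, noise_sls = 0)
  f <- fit_virial(gen_sls(cfg))
  # ideal limit: constant RT/Mw
  cfg0 <- generator_config(seed = 3, noise_sls = 0,
                           sls = list(Mw = 2e4, A2 = 0, A3 = 0))
  f0 <- fit_virial(gen_sls(cfg0))
  d <- osmotic_pressure_derivative(f0, c(0.02, 0.05, 0.09))
  expect_equal(d, rep(R_GAS * 298.15 / f0$Mw_app, 3), tolerance = 1e-6)
  # A2 > 0: strictly increasing in c
  cc <- seq(0.015, 0.09, length.out = 20)
  expect_true(all(diff(osmotic_pressure_derivative(f, cc)) > 0))
  # centered finite difference of the integrated Pi(c)
  Pi_of <- function(ch) stats::integrate(function(u)
    osmotic_pressure_derivative(f, u), 0.02, ch, rel.tol = 1e-12)$value
  h <- 1e-6
  fd <- (Pi_of(0.05 + h) - Pi_of(0.05 - h)) / (2 * h)
  expect_equal(osmotic_pressure_derivative(f, 0.05), fd, tolerance = 1e-6)
  expect_error(osmotic_pressure_derivative(f, -0.01), "positive")
})

test_that("excess free energy: limits, closed form vs quadrature, monotone", {
  cfg <- generator_config(seed = 3, noise_sls = 0)
  f <- fit_virial(gen_sls(cfg))
  expect_equal(as.numeric(free_energy_excess(f, 0.03, 0.03, 193.25, 298.15)), 0)
  # ideal fit with Mw = M: exactly kB T log(cH/cL)
  s_id <- gen_sls(generator_config(seed = 3, noise_sls = 0,
                                   sls = list(Mw = 193.25, A2 = 0, A3 = 0)))
  f_id <- fit_virial(s_id)
  dg <- free_energy_excess(f_id, 0.02, 0.08, molar_mass = 193.25,
                           temperature = 298.15)
  expect_equal(as.numeric(dg), kB * 298.15 * log(4), tolerance = 1e-9)
  expect_equal(attr(dg, "kBT"), log(4), tolerance = 1e-9)
  # closed form vs quadrature on random virial parameter draws
  set.seed(42)
  for (i in 1:20) {
    fi <- f
    fi$Mw_app <- stats::runif(1, 1e3, 1e6)
    fi$A2 <- stats::runif(1, -1e-4, 1e-3)
    fi$A3 <- stats::runif(1, 0, 1e-3)
    cl <- stats::runif(1, 0.005, 0.03)
    ch <- cl + stats::runif(1, 0, 0.07)
    a <- free_energy_excess(fi, cl, ch, 193.25, 298.15)
    b <- free_energy_excess(fi, cl, ch, 193.25, 298.15, method = "quadrature")
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-8)
  }
  # monotone nondecreasing in c_H while Kc/R_theta > 0
  curve <- free_energy_curve(f, seq(0.011, 0.095, length.out = 40),
                             molar_mass = 193.25)
  expect_true(all(diff(curve$dg_J) > 0))
  expect_equal(curve$dg_J[1L], 0)
  expect_error(free_energy_excess(f, 0.05, 0.02, 193.25, 298.15), "exceed")
  expect_error(free_energy_excess(f, 0, 0.02, 193.25, 298.15), "divergent")
})
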
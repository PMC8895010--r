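test_that("speciation closed form agrees with the bisection oracle", {
  set.seed(7)
  err <- vapply(1:1000, function(i) {
    kd <- stats::runif(1, 0, 50)
    cc <- stats::runif(1, 1e-3, 2)  # uniroot's absolute x-tolerance limits
                                    # the oracle's relative precision below this
    sp <- speciate(kd, cc)
    or <- speciate_bisect(kd, cc)
    max(abs(sp$monomer - or$monomer) / or$monomer,
        abs(sp$dimer - or$dimer) / max(or$dimer, 1e-30),
        abs(sp$monomer + 2 * sp$dimer - cc) / cc,          # mass balance
        abs(kd * sp$monomer^2 - sp$dimer) / max(sp$dimer, 1e-30))
  }, numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("speciation limits and the reference composition at 0.5 M", {
  expect_equal(speciate(0, 0.3)$dimer, 0)
  expect_equal(speciate(0, 0.3)$monomer, 0.3)
  expect_equal(speciate(1.147, 0)$dimer, 0)
  sp <- speciate(1.147, 0.5)
  expect_equal(sp$monomer, 0.297274431285, tolerance = 1e-9)
  expect_equal(sp$dimer, 0.101362784358, tolerance = 1e-9)
  expect_true(sp$frac_molecules_in_dimers >= 0 &&
                sp$frac_molecules_in_dimers <= 1)
  expect_true(sp$frac_dimer_species >= 0 && sp$frac_dimer_species <= 1)
  expect_error(speciate(-1, 0.5), "nonnegative")
})

test_that("the fast-exchange isotherm respects its limits and bounds", {
  expect_equal(shift_model(1.147, 130, 130.5, 1e-10), 130, tolerance = 1e-8)
  expect_equal(shift_model(1.147, 131.2, 131.2, c(0.1, 0.4)), c(131.2, 131.2))
  # weight = 2[D]/c at the reference composition
  expect_equal(shift_model(1.147, 130, 130.5, 0.5), 130.202725569,
               tolerance = 1e-9)
  cc <- seq(0.01, 1, length.out = 50)
  d <- shift_model(2, 130, 130.5, cc)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 130 & d <= 130.5))
})

test_that("dimerization constant is recovered from noiseless series", {
  cfg <- generator_config(seed = 5, noise_shift = 0)
  fit <- fit_dimerization(gen_nmr_shifts(cfg))
  expect_equal(fit$k_D, 1.147, tolerance = 5e-3)   # <0.5% relative
  expect_equal(fit$per_carbon$delta_M, c(112.500, 131.200, 145.800),
               tolerance = 1e-5)
  expect_equal(fit$per_carbon$delta_D, c(112.775, 132.026, 147.176),
               tolerance = 1e-5)
  expect_false(fit$flat_model)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("noisy recovery stays within 5% with high pooled R-squared", {
  cfg <- generator_config(seed = 1)
  fit <- fit_dimerization(gen_nmr_shifts(cfg))
  expect_lt(abs(fit$k_D - 1.147) / 1.147, 0.05)
  expect_gt(fit$r_squared, 0.98)
  expect_true(fit$converged)
  expect_true(is.finite(fit$k_D_se))
})

test_that("association-free data trip the flat-model diagnostic", {
  cfg <- generator_config(seed = 9, nmr = list(
    k_D = 0,
    carbons = data.frame(carbon = "C18", delta_M = 19.8, delta_D = 19.8)))
  expect_warning(fit <- fit_dimerization(gen_nmr_shifts(cfg)),
                 "flat|not identified|concentration-independent")
  expect_true(fit$flat_model)
})

test_that("per-carbon independent fits are available as a diagnostic", {
  cfg <- generator_config(seed = 4, noise_shift = 0)
  fits <- fit_dimerization(gen_nmr_shifts(cfg), shared_kD = FALSE)
  expect_length(fits, 3L)
  for (f in fits) expect_equal(f$k_D, 1.147, tolerance = 1e-2)
})

test_that("k_D recovery holds across 100 seeded noisy replicates", {
  kd_hat <- vapply(1:100, function(i) {
    fit_dimerization(gen_nmr_shifts(generator_config(seed = 2000 + i)))$k_D
  }, numeric(1))
  frac_within <- mean(abs(kd_hat - 1.147) / 1.147 <= 0.10)
  expect_gte(frac_within, 0.95)
})

test_that("population curves are monotone and consistent with speciate", {
  grid <- seq(0.01, 0.5, length.out = 30)
  pc <- population_curve(1.147, grid)
  expect_true(all(diff(pc$frac_molecules_in_dimers) > 0))
  expect_true(all(diff(pc$frac_dimer_species) > 0))
  monomer_frac <- 1 - pc$frac_molecules_in_dimers
  expect_true(all(diff(monomer_frac) < 0))
  # pointwise agreement with speciate
  i <- c(1L, 15L, 30L)
  sp <- speciate(1.147, grid[i])
  expect_equal(pc$frac_molecules_in_dimers[i], sp$frac_molecules_in_dimers)
  # dimer fraction vanishes at infinite dilution
  expect_lt(speciate(1.147, 1e-9)$frac_molecules_in_dimers, 1e-8)
})
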
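test_that("reaction kinetics conserve molecules exactly and fix equilibrium", {
  set.seed(3)
  for (i in 1:50) {
    n1 <- stats::runif(1, 0, 1e27)
    n2 <- stats::runif(1, 0, 1e26)
    k1 <- stats::runif(1, 0, 1e-25)
    k2 <- stats::runif(1, 0, 1e6)
    r <- reaction_rates(n1, n2, k1, k2)
    expect_identical(r$dn1 + 2 * r$dn2, 0)   # exact, not approximate
  }
  # equilibrium densities are a fixed point (relative to the one-way rate)
  k1 <- kd_to_rate_ratio(1.147) * 1e5
  n1 <- 1e26
  n2 <- k1 * n1^2 / 1e5
  r <- reaction_rates(n1, n2, k1, 1e5)
  expect_lt(abs(r$dn1) / (2 * k1 * n1^2), 1e-12)
  expect_lt(abs(r$dn2) / (k1 * n1^2), 1e-12)
  # pure formation when no dimers exist
  r0 <- reaction_rates(1e26, 0, 1e-27, 1e5)
  expect_equal(r0$dn2, 1e-27 * 1e52)
  expect_gt(r0$dn2, 0)
})

test_that("closed-box reaction integration conserves mass and equilibrates", {
  # independent stiff-integrator oracle on the 0-D kinetics
  k1 <- kd_to_rate_ratio(1.147) * 1.25e5
  k2 <- 1.25e5
  rhs <- function(t, y, p) {
    r <- reaction_rates(y[1L], y[2L], k1, k2)
    list(c(r$dn1, r$dn2))
  }
  y0 <- c(2.5e26, 1e25)   # far from equilibrium
  sol <- deSolve::ode(y0, times = c(0, 10^seq(-7, -2, length.out = 20)),
                      rhs, NULL, method = "lsoda", rtol = 1e-10, atol = 1e10)
  total <- sol[, 2L] + 2 * sol[, 3L]
  expect_lt(max(abs(total - total[1L])) / total[1L], 1e-9)
  n1_end <- sol[nrow(sol), 2L][[1L]]
  n2_end <- sol[nrow(sol), 3L][[1L]]
  expect_equal(k1 * n1_end^2, k2 * n2_end, tolerance = 1e-6)
})

test_that("unit plumbing between molar and number-density conventions", {
  expect_equal(kd_to_rate_ratio(1.147), 1.147 / 6.02214076e26,
               tolerance = 1e-12)
  expect_identical(kd_to_rate_ratio(0), 0)
  expect_equal(molar_to_number_density(1), 6.02214076e26)
  expect_equal(number_density_to_molar(molar_to_number_density(0.37)), 0.37,
               tolerance = 1e-14)
})

test_that("decay rate from cluster radius and the screening length invert", {
  expect_equal(decay_rate_from_radius(3.2e-11, 16e-9), 125000)
  # R^-2 scaling
  expect_equal(decay_rate_from_radius(3.2e-11, 4 * 16e-9), 125000 / 16)
  expect_equal(screening_length(3.2e-11, 125000), 1.6e-8, tolerance = 1e-12)
  expect_equal(screening_length(3.2e-11, decay_rate_from_radius(3.2e-11, 1e-8)),
               1e-8, tolerance = 1e-12)
})

test_that("rd_params completes k1 from equilibrium and checks it", {
  p <- default_rd_params()
  expect_equal(p$k1 * p$n1_inf^2, p$k2 * p$n2_inf, tolerance = 1e-12)
  expect_error(rd_params(k2 = 1e5, D1 = 4e-11, D2 = 3.2e-11,
                         n1_inf = 1e26, n2_inf = 1e25, k1 = 1e-30),
               "equilibrium")
})

test_that("zero contrast leaves the bulk unperturbed", {
  p <- default_rd_params()
  prof <- steady_profiles(p, R_cluster = 16e-9, core_contrast = 0)
  expect_equal(prof$n1, rep(p$n1_inf, nrow(prof)), tolerance = 1e-14)
  expect_equal(prof$n2, rep(p$n2_inf, nrow(prof)), tolerance = 1e-14)
})

test_that("steady profiles have the cluster shape and exact flux balance", {
  p <- default_rd_params()
  prof <- steady_profiles(p, R_cluster = 16e-9, core_contrast = 1.5)
  lam <- attr(prof, "lambda_screen")
  expect_equal(lam, 1.6e-8, tolerance = 1e-12)
  # dimers enriched and monomers depleted inside; monotone relaxation outward
  expect_true(all(diff(prof$n2) <= 1e-12 * p$n2_inf))
  expect_true(all(diff(prof$n1) >= -1e-12 * p$n1_inf))
  expect_gt(prof$n2[1L], p$n2_inf)
  expect_lt(prof$n1[1L], p$n1_inf)
  expect_true(all(prof$n1 >= 0) && all(prof$n2 >= 0))
  # far field approaches the bulk within 1e-3 relative at r = 10 Lambda
  i10 <- which.min(abs(prof$r - 10 * lam))
  expect_lt(abs(prof$n2[i10] - p$n2_inf) / p$n2_inf, 1e-3)
  expect_lt(abs(prof$n1[i10] - p$n1_inf) / p$n1_inf, 1e-3)
  # steady-state flux-balance identity, pointwise
  ident <- p$D1 * (prof$n1 - p$n1_inf) + 2 * p$D2 * (prof$n2 - p$n2_inf)
  expect_lt(max(abs(ident)) / (p$D2 * p$n2_inf), 1e-12)
  # no discontinuity at the matching radius: evaluate on a grid straddling R
  fine <- sort(c(16e-9 * (1 - 1e-9), 16e-9 * (1 + 1e-9),
                 seq(1e-9, 1.5e-7, length.out = 50)))
  pf <- steady_profiles(p, 16e-9, 1.5, r_grid = fine)
  jl <- which(abs(pf$r - 16e-9 * (1 - 1e-9)) < 1e-18)
  expect_equal(pf$n2[jl], pf$n2[jl + 1L], tolerance = 1e-6)
})

test_that("profile shape is invariant across the core-contrast sweep", {
  # dilute condition so the documented sweep range is attainable unclipped
  p <- default_rd_params(conc_M = 0.01)
  shapes <- lapply(c(3, 10, 35), function(ct) {
    pr <- steady_profiles(p, 16e-9, ct)
    d2 <- pr$n2 - p$n2_inf
    d2 / d2[1L]                           # normalized excess
  })
  expect_equal(shapes[[1L]], shapes[[2L]], tolerance = 1e-10)
  expect_equal(shapes[[2L]], shapes[[3L]], tolerance = 1e-10)
  # over-strong contrast is clipped with a warning, densities stay physical
  pdense <- default_rd_params(conc_M = 0.5)
  expect_warning(pr <- steady_profiles(pdense, 16e-9, 35), "clipped")
  expect_true(all(pr$n1 >= -1e-6 * pdense$n1_inf))
})

test_that("analytic steady profile matches the finite-difference BVP oracle", {
  p <- default_rd_params()
  contrast <- 1.5
  R <- 16e-9
  bvp <- bvp_screened_profile(p$D2, p$k2, R, contrast, p$n2_inf)
  ana <- steady_profiles(p, R, contrast, r_grid = bvp$r)  # same nodes
  keep <- bvp$r < 10 * bvp$lambda
  scale <- contrast * p$n2_inf
  expect_lt(max(abs((ana$n2 - p$n2_inf)[keep] - bvp$delta2[keep])) / scale,
            1e-3)
})

test_that("grid and argument validation in steady_profiles", {
  p <- default_rd_params()
  expect_error(steady_profiles(p, 1e-6, 1), "span")
  expect_error(steady_profiles(p, 16e-9, -1), "nonnegative")
})

test_that("uniform equilibrium initial condition is stationary under evolution", {
  p <- default_rd_params()
  lam <- screening_length(p$D2, p$k2)
  grid <- exp(seq(log(0.1 * lam), log(10 * lam), length.out = 80))
  evo <- evolve_rd(p, grid, rep(p$n1_inf, 80), rep(p$n2_inf, 80),
                   t_end = 1e-4, n_times = 10)
  expect_lt(max(abs(evo$n1 - p$n1_inf)) / p$n1_inf, 1e-7)
  expect_lt(max(abs(evo$n2 - p$n2_inf)) / p$n2_inf, 1e-7)
})

test_that("closed-box evolution conserves total molecule content", {
  p <- default_rd_params()
  lam <- screening_length(p$D2, p$k2)
  grid <- exp(seq(log(0.1 * lam), log(10 * lam), length.out = 80))
  # start well off equilibrium: a dimer-rich gaussian blob
  n2_0 <- p$n2_inf * (1 + 2 * exp(-(grid / (2 * lam))^2))
  evo <- evolve_rd(p, grid, rep(p$n1_inf, 80), n2_0, t_end = 1e-3,
                   outer_bc = "closed", rtol = 1e-10, atol_scale = 1e-12)
  expect_lt(max(abs(evo$mass - evo$mass[1L])) / evo$mass[1L], 1e-6)
})

test_that("open-system relaxation reproduces the analytic steady profile", {
  p <- default_rd_params()
  lam <- screening_length(p$D2, p$k2)
  grid <- exp(seq(log(0.05 * lam), log(12 * lam), length.out = 140))
  R <- 16e-9; contrast <- 1.5
  evo <- evolve_rd(p, grid, rep(p$n1_inf, 140), rep(p$n2_inf, 140),
                   t_end = 1e-3, cluster_R = R, core_contrast = contrast,
                   linearize = TRUE)
  target <- steady_profiles(p, R, contrast, r_grid = grid)
  fin <- final_profile(evo)
  l2 <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(l2(fin$n2, target$n2) / l2(target$n2, rep(p$n2_inf, 140)), 0.01)
  expect_lt(l2(fin$n1, target$n1) / l2(target$n1, rep(p$n1_inf, 140)), 0.01)
})
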
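#' Monomer-dimer reaction rates
#'
#' Local mass-action kinetics of the dimerization reaction 2M <-> D:
#' \deqn{dn_1/dt = -2 k_1 n_1^2 + 2 k_2 n_2, \qquad
#'       dn_2/dt = k_1 n_1^2 - k_2 n_2.}
#' Every dimer formed consumes two monomers, so the combination
#' `dn1/dt + 2 dn2/dt` vanishes identically (molecule conservation).
#'
#' @param n1,n2 monomer and dimer number densities (m^-3), nonnegative;
#'   vectorized.
#' @param k1 dimer formation rate constant (m^3/s per number-density pair).
#' @param k2 dimer decay rate constant (1/s).
#' @return list with elements `dn1` and `dn2` (m^-3 s^-1).
#' @export
reaction_rates <- function(n1, n2, k1, k2) {
  .check_nonnegative(n1, n2, k1, k2)
  form <- k1 * n1^2
  decay <- k2 * n2
  list(dn1 = -2 * form + 2 * decay, dn2 = form - decay)
}

#' Convert molar concentrations and number densities
#'
#' 1 M = 1 mol/l = `N_A * 1e3` molecules per m^3.
#'
#' @param c_M concentration in mol/l.
#' @return number density in m^-3.
#' @export
molar_to_number_density <- function(c_M) {
  .check_nonnegative(c_M)
  c_M * N_AVOGADRO * 1e3
}

#' @rdname molar_to_number_density
#' @param n number density in m^-3.
#' @export
number_density_to_molar <- function(n) {
  .check_nonnegative(n)
  n / (N_AVOGADRO * 1e3)
}

#' Rate-constant ratio implied by a molar dimerization constant
#'
#' At bulk chemical equilibrium `k1 n1^2 = k2 n2`, so
#' `k1/k2 = n2/n1^2 = k_D / (N_A * 1e3)` in m^3: the molar equilibrium
#' constant divided by the molar-to-number-density factor.
#'
#' @param k_D dimerization constant in 1/M.
#' @return `k1/k2` in m^3.
#' @export
kd_to_rate_ratio <- function(k_D) {
  .check_nonnegative(k_D)
  k_D / (N_AVOGADRO * 1e3)
}

#' Dimer decay rate from the cluster radius
#'
#' In the steady-state spherical solution the dimer-density excess decays
#' outside the cluster over the screening length `Lambda = sqrt(D2/k2)`.
#' Identifying that decay length with the cluster radius fixes the decay
#' rate constant:
#' \deqn{k_2 = D_2 / R^2.}
#' `k_2` depends only on the dimer mobility and the cluster size, not on the
#' solute concentration.
#'
#' @param D2 dimer diffusion coefficient in m^2/s.
#' @param R_cluster cluster radius in m.
#' @return decay rate constant `k2` in 1/s.
#' @seealso [screening_length()] for the inverse relation.
#' @export
#' @examples
#' decay_rate_from_radius(3.2e-11, 16e-9)  # 1.25e5 s^-1
decay_rate_from_radius <- function(D2, R_cluster) {
  .check_positive(D2, R_cluster)
  D2 / R_cluster^2
}

#' Dimer screening (decay) length
#'
#' `Lambda = sqrt(D2/k2)`, the distance over which a dimer-density
#' perturbation decays in the bulk; inverse of [decay_rate_from_radius()].
#'
#' @param D2 dimer diffusion coefficient in m^2/s.
#' @param k2 dimer decay rate constant in 1/s.
#' @return screening length in m.
#' @export
screening_length <- function(D2, k2) {
  .check_positive(D2, k2)
  sqrt(D2 / k2)
}

#' Reaction-diffusion parameter bundle
#'
#' Collects the rate constants, diffusion coefficients and bulk densities of
#' the monomer-dimer reaction-diffusion model. When `k1` is omitted it is
#' completed from bulk chemical equilibrium `k1 n1_inf^2 = k2 n2_inf`;
#' when supplied, the equilibrium condition is checked to 1e-9 relative
#' (pass `equilibrated = FALSE` to store deliberately off-equilibrium bulk
#' densities).
#'
#' @param k2 dimer decay rate constant, 1/s.
#' @param D1,D2 monomer and dimer diffusion coefficients, m^2/s.
#' @param n1_inf,n2_inf bulk monomer and dimer number densities, m^-3.
#' @param k1 dimer formation rate constant, m^3/s; default from equilibrium.
#' @param equilibrated whether the bulk densities are asserted to be in
#'   chemical equilibrium.
#' @return An object of class `rd_params`.
#' @export
#' @examples
#' sp <- speciate(1.147, 0.5)
#' rd_params(k2 = 1.25e5, D1 = 4e-11, D2 = 3.2e-11,
#'           n1_inf = molar_to_number_density(sp$monomer),
#'           n2_inf = molar_to_number_density(sp$dimer))
rd_params <- function(k2, D1, D2, n1_inf, n2_inf, k1 = NULL,
                      equilibrated = TRUE) {
  .check_positive(k2, D1, D2, n1_inf, n2_inf)
  if (is.null(k1)) {
    k1 <- k2 * n2_inf / n1_inf^2
  } else {
    .check_nonnegative(k1)
    if (equilibrated &&
        abs(k1 * n1_inf^2 - k2 * n2_inf) > 1e-9 * k2 * n2_inf) {
      stop("bulk densities violate chemical equilibrium k1*n1_inf^2 = k2*n2_inf",
           call. = FALSE)
    }
  }
  structure(list(k1 = k1, k2 = k2, D1 = D1, D2 = D2,
                 n1_inf = n1_inf, n2_inf = n2_inf,
                 equilibrated = equilibrated),
            class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat("<rd_params>\n")
  cat(sprintf("  k1 = %.4g m^3/s, k2 = %.4g 1/s\n", x$k1, x$k2))
  cat(sprintf("  D1 = %.4g, D2 = %.4g m^2/s\n", x$D1, x$D2))
  cat(sprintf("  n1_inf = %.4g, n2_inf = %.4g m^-3 (Lambda = %.3g m)\n",
              x$n1_inf, x$n2_inf, screening_length(x$D2, x$k2)))
  invisible(x)
}

# interior/exterior basis functions of the screened spherical problem
.sph_sinh <- function(r, lambda) {
  x <- r / lambda
  ifelse(x < 1e-8, 1 + x^2 / 6, sinh(x) / x)   # regular at the origin
}
.sph_sinh_prime <- function(r, lambda) {       # d/dr of .sph_sinh
  x <- r / lambda
  (cosh(x) / r) - (lambda * sinh(x) / r^2)
}

# matching amplitudes of the piecewise steady dimer excess:
#   interior  delta2(r) = P0 + a * sinh(r/L)/(r/L)
#   exterior  delta2(r) = B * (R/r) * exp(-(r-R)/L)
# matched in value and flux at R, with delta2(0) = contrast * n2_inf
.steady_amplitudes <- function(lambda, R, contrast, n2_inf) {
  uR <- .sph_sinh(R, lambda)
  upR <- .sph_sinh_prime(R, lambda)
  vpR <- -(1 / R + 1 / lambda)                 # v(R) = 1
  denom <- 1 + (vpR / upR) * (1 - uR)
  B <- contrast * n2_inf / denom
  a <- B * vpR / upR
  P0 <- B - a * uR
  list(B = B, a = a, P0 = P0)
}

#' Steady-state monomer/dimer density profiles around a cluster
#'
#' Solves the linearized steady spherical reaction-diffusion problem for the
#' dimer-density excess `delta2 = n2 - n2_inf`. In the bulk (dilute dimers,
#' monomer bath at its equilibrium value) the excess obeys the screened
#' equation `D2 Laplacian(delta2) = k2 delta2`, whose solutions are the
#' Yukawa-type exterior mode `(R/r) exp(-(r-R)/Lambda)` and the interior mode
#' `sinh(r/Lambda)/(r/Lambda)` regular at the origin, with
#' `Lambda = sqrt(D2/k2)`. Inside the cluster (r < R) the monomer-to-dimer
#' conversion is enhanced by the thermodynamic drive; this is modeled as a
#' constant excess conversion source, which shifts the interior solution by a
#' plateau. The three amplitudes (plateau, interior mode, exterior mode) are
#' fixed by continuity of value and diffusive flux at `R` plus the prescribed
#' core contrast `delta2(0) = core_contrast * n2_inf`.
#'
#' The monomer field follows from the exact steady-state identity
#' `D1 Laplacian(n1) + 2 D2 Laplacian(n2) = 0` (summing the two steady
#' equations, the reaction terms cancel): the harmonic combination
#' `D1 delta1 + 2 D2 delta2` is bounded and vanishes at infinity, hence is
#' identically zero, giving `delta1 = -(2 D2/D1) delta2`. Dimers are therefore
#' enriched and monomers depleted inside the cluster, with smooth profiles and
#' no sharp boundary at `R`.
#'
#' @param params an [rd_params()] bundle (equilibrated bulk).
#' @param R_cluster cluster radius in m; must lie inside `r_grid`.
#' @param core_contrast ratio of the central dimer excess to the bulk dimer
#'   density, `delta2(0)/n2_inf`, >= 0. Contrasts so large that the monomer
#'   field would go negative at the center are clipped with a warning.
#' @param r_grid radial grid in m, strictly increasing, > 0; defaults to 200
#'   points log-spaced over `[0.1, 10] * Lambda` around the cluster.
#' @return An object of class `spatial_profile`: data frame with columns `r`,
#'   `n1`, `n2` and attributes `R_cluster`, `lambda_screen`, `B` (exterior
#'   matching amplitude), `core_plateau`, `core_contrast`, `params`.
#' @export
#' @examples
#' sp <- speciate(1.147, 0.5)
#' p <- rd_params(k2 = 1.25e5, D1 = 4e-11, D2 = 3.2e-11,
#'                n1_inf = molar_to_number_density(sp$monomer),
#'                n2_inf = molar_to_number_density(sp$dimer))
#' prof <- steady_profiles(p, R_cluster = 16e-9, core_contrast = 10)
steady_profiles <- function(params, R_cluster, core_contrast,
                            r_grid = NULL) {
  stopifnot(inherits(params, "rd_params"))
  .check_positive(R_cluster)
  .check_nonnegative(core_contrast)
  lambda <- screening_length(params$D2, params$k2)
  if (is.null(r_grid)) {
    r_grid <- exp(seq(log(0.1 * lambda), log(10 * lambda), length.out = 200L))
  }
  .check_positive(r_grid)
  if (any(diff(r_grid) <= 0)) {
    stop("'r_grid' must be strictly increasing", call. = FALSE)
  }
  if (R_cluster <= r_grid[1L] || R_cluster >= r_grid[length(r_grid)]) {
    stop("'r_grid' must span the cluster radius", call. = FALSE)
  }
  # clip contrasts that would drive the central monomer density negative
  max_contrast <- params$n1_inf * params$D1 / (2 * params$D2 * params$n2_inf)
  if (core_contrast > max_contrast) {
    warning(sprintf(
      "core_contrast clipped from %.3g to %.3g to keep densities nonnegative",
      core_contrast, max_contrast), call. = FALSE)
    core_contrast <- max_contrast
  }
  amp <- .steady_amplitudes(lambda, R_cluster, core_contrast, params$n2_inf)
  inside <- r_grid <= R_cluster
  delta2 <- numeric(length(r_grid))
  delta2[inside] <- amp$P0 + amp$a * .sph_sinh(r_grid[inside], lambda)
  delta2[!inside] <- amp$B * (R_cluster / r_grid[!inside]) *
    exp(-(r_grid[!inside] - R_cluster) / lambda)
  delta1 <- -(2 * params$D2 / params$D1) * delta2
  structure(data.frame(r = r_grid,
                       n1 = params$n1_inf + delta1,
                       n2 = params$n2_inf + delta2),
            R_cluster = R_cluster,
            lambda_screen = lambda,
            B = amp$B,
            core_plateau = amp$P0,
            core_contrast = core_contrast,
            params = params,
            class = c("spatial_profile", "data.frame"))
}

# conservative finite-volume spherical Laplacian operator pieces for a
# nonuniform grid: face radii, face areas and cell volumes (4*pi omitted)
.fv_geometry <- function(r) {
  n <- length(r)
  rf <- c(max(r[1L] - (r[2L] - r[1L]) / 2, 0),
          (r[-n] + r[-1L]) / 2,
          r[n] + (r[n] - r[n - 1L]) / 2)
  list(rf = rf,
       area = rf^2,
       vol = diff(rf^3) / 3)
}

#' Time-dependent spherical reaction-diffusion evolution
#'
#' Integrates the monomer/dimer density fields
#' \deqn{\partial_t n_1 = D_1 \nabla^2 n_1 - 2k_1 n_1^2 + 2k_2 n_2 - 2s(r)}
#' \deqn{\partial_t n_2 = D_2 \nabla^2 n_2 + k_1 n_1^2 - k_2 n_2 + s(r)}
#' under spherical symmetry by a conservative finite-volume method of lines
#' (implicit stiff integrator from \pkg{deSolve}). `s(r)` is the optional
#' in-cluster excess conversion source used by [steady_profiles()]; it moves
#' molecules between the species, so `n1 + 2 n2` is conserved by reaction and
#' source alike. The inner boundary is always no-flux; the outer boundary is
#' either clamped to the bulk densities (`"bulk"`, open system) or no-flux
#' (`"closed"`, conserving total molecule content to integrator tolerance).
#'
#' With `linearize = TRUE` the reaction is replaced by its monomer-bath
#' linearization `-k2 (n2 - n2_inf)` (and the mirrored term for monomers),
#' the approximation under which [steady_profiles()] is exact; an open-system
#' run then relaxes to that analytic profile.
#'
#' @param params an [rd_params()] bundle.
#' @param r_grid radial grid in m, strictly increasing.
#' @param n1_init,n2_init initial density fields on `r_grid` (m^-3).
#' @param t_end final time in s.
#' @param n_times number of output times (log-spaced after 0).
#' @param cluster_R,core_contrast when both given and positive, apply the
#'   same interior conversion source as [steady_profiles()] with this radius
#'   and contrast.
#' @param outer_bc `"bulk"` (Dirichlet at `n1_inf`, `n2_inf`) or `"closed"`
#'   (no-flux).
#' @param linearize use the monomer-bath linearized reaction.
#' @param rtol,atol_scale integrator tolerances; absolute tolerance is
#'   `atol_scale * max(bulk densities)`.
#' @return An object of class `rd_evolution`: list with `times`, `r`, `n1`
#'   and `n2` (time-by-radius matrices), `mass` (total molecule content
#'   `integral (n1 + 2 n2) dV` per output time, 4 pi omitted) and the call
#'   parameters.
#' @export
evolve_rd <- function(params, r_grid, n1_init, n2_init, t_end,
                      n_times = 40L, cluster_R = NULL, core_contrast = 0,
                      outer_bc = c("bulk", "closed"), linearize = FALSE,
                      rtol = 1e-8, atol_scale = 1e-10) {
  stopifnot(inherits(params, "rd_params"))
  outer_bc <- match.arg(outer_bc)
  .check_positive(r_grid, t_end)
  if (any(diff(r_grid) <= 0)) {
    stop("'r_grid' must be strictly increasing", call. = FALSE)
  }
  N <- length(r_grid)
  if (length(n1_init) != N || length(n2_init) != N) {
    stop("initial fields must match the grid length", call. = FALSE)
  }
  geo <- .fv_geometry(r_grid)
  dr <- diff(r_grid)
  lambda <- screening_length(params$D2, params$k2)

  src <- numeric(N)
  if (!is.null(cluster_R) && core_contrast > 0) {
    amp <- .steady_amplitudes(lambda, cluster_R, core_contrast, params$n2_inf)
    # volumetric overlap of each finite-volume cell with the cluster sphere,
    # so the discrete source converges to the sharp continuum source
    overlap <- pmax(pmin(geo$rf[-1L], cluster_R)^3 -
                      pmin(geo$rf[-(N + 1L)], cluster_R)^3, 0) / 3
    src <- params$k2 * amp$P0 * overlap / geo$vol
  }

  lap_flux <- function(n, D, n_bulk) {
    # interior face diffusive fluxes D * dn/dr (positive outward gradient)
    f_int <- D * diff(n) / dr
    f_out <- switch(outer_bc,
                    bulk = D * (n_bulk - n[N]) / dr[N - 1L],
                    closed = 0)
    f <- c(0, f_int, f_out)                    # no-flux inner boundary
    diff(geo$area * f) / geo$vol
  }

  k1 <- params$k1; k2 <- params$k2
  n1_inf <- params$n1_inf; n2_inf <- params$n2_inf
  deriv <- function(t, y, parms) {
    n1 <- y[1:N]; n2 <- y[(N + 1):(2 * N)]
    if (linearize) {
      decay_net <- k2 * (n2 - n2_inf)
      dn1 <- lap_flux(n1, params$D1, n1_inf) + 2 * decay_net - 2 * src
      dn2 <- lap_flux(n2, params$D2, n2_inf) - decay_net + src
    } else {
      form <- k1 * pmax(n1, 0)^2
      decay <- k2 * pmax(n2, 0)
      dn1 <- lap_flux(n1, params$D1, n1_inf) - 2 * form + 2 * decay - 2 * src
      dn2 <- lap_flux(n2, params$D2, n2_inf) + form - decay + src
    }
    list(c(dn1, dn2))
  }
  times <- c(0, exp(seq(log(t_end / 1e4), log(t_end), length.out = n_times - 1L)))
  atol <- atol_scale * max(n1_inf, n2_inf)
  sol <- deSolve::ode.1D(y = c(n1_init, n2_init), times = times, func = deriv,
                         parms = NULL, nspec = 2L, dimens = N,
                         method = "lsodes", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("stiff integrator failed; refine the grid or relax t_end", call. = FALSE)
  }
  n1_mat <- sol[, 1 + 1:N, drop = FALSE]
  n2_mat <- sol[, 1 + (N + 1):(2 * N), drop = FALSE]
  mass <- as.numeric((n1_mat + 2 * n2_mat) %*% geo$vol)
  structure(list(times = sol[, 1L], r = r_grid,
                 n1 = n1_mat, n2 = n2_mat, mass = mass,
                 params = params, outer_bc = outer_bc,
                 linearize = linearize),
            class = "rd_evolution")
}

#' Final spatial profile of an evolution run
#'
#' @param evo an [evolve_rd()] result.
#' @return a `spatial_profile`-shaped data frame (`r`, `n1`, `n2`) at the
#'   last output time.
#' @export
final_profile <- function(evo) {
  stopifnot(inherits(evo, "rd_evolution"))
  k <- nrow(evo$n1)
  data.frame(r = evo$r, n1 = evo$n1[k, ], n2 = evo$n2[k, ])
}
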
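#' Cluster-radius evolution model
#'
#' Two-term radius dynamics of a dimer-rich cluster,
#' \deqn{\frac{dR}{dt} = \frac{D_2}{R}\,\sigma_d - \frac{k_2}{3}\,\chi\,R,}
#' where the first term is the diffusive growth drive supplied by dimers in
#' solution (a dimensionless thermodynamic drive coefficient `drive` =
#' sigma_d multiplying the diffusive velocity scale `D2/R`) and the second is
#' reaction-limited shrinkage: dimers in excess of local equilibrium convert
#' back to monomers at rate `k2` and the monomers are expelled, eroding the
#' cluster volume (shrink coefficient `shrink` = chi, default 1). Small
#' clusters grow, large clusters shrink, and the radius stabilizes at the
#' unique fixed point
#' \deqn{R^* = \sqrt{3\sigma_d D_2 / (\chi k_2)}.}
#' The default `drive = 1/3` makes `R*` coincide with the dimer screening
#' length `sqrt(D2/k2)` of [steady_profiles()], the package's documented
#' cross-module consistency convention.
#'
#' @param D2 dimer diffusion coefficient, m^2/s.
#' @param k2 dimer decay rate constant, 1/s.
#' @param drive dimensionless growth-drive coefficient sigma_d, >= 0.
#' @param shrink dimensionless shrink coefficient chi, >= 0.
#' @return An object of class `radius_model`.
#' @export
#' @examples
#' m <- radius_model(D2 = 3.2e-11, k2 = 1.25e5)
#' steady_radius(m)  # 16 nm
radius_model <- function(D2, k2, drive = 1 / 3, shrink = 1) {
  .check_positive(D2, k2)
  .check_nonnegative(drive, shrink)
  structure(list(D2 = D2, k2 = k2, drive = drive, shrink = shrink),
            class = "radius_model")
}

#' Radius growth rate dR/dt
#'
#' @param R cluster radius in m, > 0; vectorized.
#' @param model a [radius_model()].
#' @return dR/dt in m/s: positive below the fixed point, negative above it.
#' @export
radius_rhs <- function(R, model) {
  stopifnot(inherits(model, "radius_model"))
  .check_positive(R)
  (model$D2 / R) * model$drive - (model$k2 / 3) * model$shrink * R
}

#' Stable steady cluster radius
#'
#' Root of [radius_rhs()]: `R* = sqrt(3 * drive * D2 / (shrink * k2))`.
#' `dR/dt` is strictly decreasing in `R`, so the fixed point is unique and
#' globally attracting on `R > 0`.
#'
#' @param model a [radius_model()] with positive `drive` and `shrink`.
#' @return `R*` in m.
#' @export
steady_radius <- function(model) {
  stopifnot(inherits(model, "radius_model"))
  if (model$shrink <= 0) {
    stop("no fixed point: 'shrink' must be positive", call. = FALSE)
  }
  if (model$drive <= 0) {
    stop("no positive fixed point: 'drive' must be positive", call. = FALSE)
  }
  sqrt(3 * model$drive * model$D2 / (model$shrink * model$k2))
}

#' Integrate the cluster-radius trajectory
#'
#' Integrates [radius_rhs()] from `R0` with an adaptive implicit scheme
#' (relative tolerance 1e-8); the `1/R` singularity is guarded by a 1 pm
#' floor. The trajectory approaches `R*` monotonically from either side;
#' `t_99` is the first output time at which `|R - R*| <= 0.01 R*`.
#'
#' @param R0 initial radius in m, > 0.
#' @param model a [radius_model()].
#' @param t_end final time in s.
#' @param n_times number of output times (log-spaced; includes t = 0).
#' @return An object of class `radius_trajectory`: data frame with columns
#'   `t` and `R`, attributes `R_steady` and `t_99`.
#' @export
#' @examples
#' m <- radius_model(3.2e-11, 1.25e5)
#' tr <- integrate_radius(1e-9, m, t_end = 1e-3)
#' attr(tr, "t_99")
integrate_radius <- function(R0, model, t_end, n_times = 400L) {
  stopifnot(inherits(model, "radius_model"))
  .check_positive(R0, t_end)
  Rstar <- steady_radius(model)
  rhs <- function(t, y, p) {
    list(radius_rhs(max(y, 1e-12), model))
  }
  times <- c(0, exp(seq(log(t_end / 1e6), log(t_end), length.out = n_times - 1L)))
  sol <- deSolve::ode(y = R0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-15)
  if (attr(sol, "istate")[1L] < 0) {
    stop("radius integration failed; reduce t_end or refine tolerances",
         call. = FALSE)
  }
  R <- sol[, 2L]
  hit <- which(abs(R - Rstar) <= 0.01 * Rstar)
  t99 <- if (length(hit)) sol[hit[1L], 1L] else NA_real_
  structure(data.frame(t = sol[, 1L], R = R),
            R_steady = Rstar,
            t_99 = t99,
            model = model,
            class = c("radius_trajectory", "data.frame"))
}

#' @export
print.radius_trajectory <- function(x, ...) {
  cat(sprintf("<radius_trajectory> %d times to %.3g s\n",
              nrow(x), x$t[nrow(x)]))
  cat(sprintf("  R_steady = %.4g m, t_99 = %.3g s, final R = %.4g m\n",
              attr(x, "R_steady"), attr(x, "t_99"), x$R[nrow(x)]))
  invisible(x)
}
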
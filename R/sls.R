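#' Optical constant for static light scattering
#'
#' Computes the SLS optical constant
#' \deqn{K = \frac{4\pi^2 n^2 (dn/dc)^2}{N_A \lambda^4}}
#' where `n` is the solvent refractive index, `dn/dc` the refractive-index
#' increment and `lambda` the vacuum wavelength. The numeric value follows the
#' units supplied: with `dndc` in ml/g and `wavelength` in cm, `K` is the
#' conventional optical constant in mol cm^2 g^-2 (ml = cm^3); the package
#' itself only relies on the scaling laws K ~ (dn/dc)^2 and K ~ lambda^-4.
#'
#' @param n_solvent solvent refractive index (dimensionless, > 0).
#' @param dndc refractive-index increment, typically ml/g (> 0).
#' @param wavelength laser vacuum wavelength (> 0).
#' @return the optical constant `K` (> 0).
#' @export
#' @examples
#' optical_constant(1.325, 0.275, 633e-7)  # lambda in cm
optical_constant <- function(n_solvent, dndc, wavelength) {
  .check_positive(n_solvent, dndc, wavelength)
  4 * pi^2 * n_solvent^2 * dndc^2 / (N_AVOGADRO * wavelength^4)
}

#' Fit the osmotic virial expansion to a Debye plot
#'
#' Fits
#' \deqn{Kc/R_\theta = 1/M_w + 2 A_2 c + 3 A_3 c^2}
#' to a static-light-scattering series by (weighted) linear least squares,
#' with `c` the mass concentration in g/ml and `Kc/R_theta` in mol/g. The
#' apparent molar mass `Mw_app` is the reciprocal intercept; `A2` and `A3`
#' are the second and third osmotic virial coefficients (mol ml g^-2 and
#' mol ml^2 g^-3). `Kc/R_theta` equals the inverse osmotic compressibility
#' `(1/RT) dPi/dc`, so this fit is the thermodynamic backbone of the
#' excess-free-energy calculation (see [free_energy_excess()]).
#'
#' With `order = "auto"` the cubic model is fitted first and dropped in favor
#' of the quadratic (two-parameter) model when the `A3` term is statistically
#' indistinguishable from zero (partial F-test at the 0.05 level).
#'
#' @param series a [concentration_series()] of Kc/R_theta (mol/g) vs mass
#'   concentration; a mass unit is required. Per-point `sigma` values, when
#'   present, enter as weights `1/sigma^2`.
#' @param order `"auto"` (default), `2` (fit `Mw`, `A2`) or `3`
#'   (fit `Mw`, `A2`, `A3`).
#' @return An object of class `virial_fit`: list with elements `Mw_app`
#'   (g/mol), `A2`, `A3`, `se` (named standard errors), `covariance`
#'   (over `Mw_app`, `A2`, `A3`, delta method for the reciprocal intercept),
#'   `fit_rss`, `order` (2 or 3), `c_range` (g/ml), `condition_number`,
#'   `temperature`, `n`.
#' @seealso [osmotic_pressure_derivative()], [free_energy_excess()]
#' @export
fit_virial <- function(series, order = c("auto", "2", "3")) {
  if (!inherits(series, "concentration_series")) {
    stop("'series' must be a concentration_series", call. = FALSE)
  }
  if (attr(series, "unit") == "M") {
    stop("SLS fitting requires a mass concentration unit (mg/ml or g/ml)",
         call. = FALSE)
  }
  order <- match.arg(as.character(order[1L]), c("auto", "2", "3"))
  c_gml <- conc_in(series, "g_per_ml")
  y <- series$value
  w <- if (!is.null(series$sigma)) 1 / series$sigma^2 else rep(1, length(y))

  n_par_max <- if (order == "2") 2L else 3L
  if (length(unique(c_gml)) < n_par_max + 2L) {
    stop(sprintf("underdetermined fit: need at least %d distinct concentrations",
                 n_par_max + 2L), call. = FALSE)
  }

  fit_one <- function(k) {            # k = polynomial order in c (1 or 2)
    X <- stats::poly(c_gml, degree = k, raw = TRUE)
    df <- data.frame(y = y, X)
    names(df) <- c("y", paste0("c", seq_len(k)))
    stats::lm(stats::reformulate(paste0("c", seq_len(k)), "y"),
              data = df, weights = w)
  }

  lm2 <- fit_one(1L)
  use_order <- 2L
  lm_used <- lm2
  if (order != "2") {
    lm3 <- fit_one(2L)
    if (any(is.na(stats::coef(lm3)))) {
      stop("degenerate data: singular design for the cubic virial model",
           call. = FALSE)
    }
    if (order == "3") {
      use_order <- 3L
      lm_used <- lm3
    } else {
      p_cubic <- .quiet_perfect_fit(stats::anova(lm2, lm3)[["Pr(>F)"]][2L])
      if (!is.na(p_cubic) && p_cubic < 0.05) {
        use_order <- 3L
        lm_used <- lm3
      }
    }
  }
  cf <- stats::coef(lm_used)
  if (any(is.na(cf))) {
    stop("degenerate data: singular design matrix", call. = FALSE)
  }
  if (cf[1L] <= 0) {
    warning("non-positive fitted intercept: apparent molar mass undefined; ",
            "check the data", call. = FALSE)
  }
  inv_Mw <- cf[[1L]]
  A2 <- cf[[2L]] / 2
  A3 <- if (use_order == 3L) cf[[3L]] / 3 else 0

  # covariance of (Mw_app, A2, A3) from the lm covariance of
  # (1/Mw, 2A2, 3A3) by the linear/delta transform J
  V <- .quiet_perfect_fit(stats::vcov(lm_used))
  k <- nrow(V)
  J <- diag(c(-1 / inv_Mw^2, 1 / 2, 1 / 3)[seq_len(k)], nrow = k)
  Vp <- J %*% V %*% t(J)
  if (k == 2L) {
    Vp <- rbind(cbind(Vp, 0), 0)
  }
  dimnames(Vp) <- list(c("Mw_app", "A2", "A3"), c("Mw_app", "A2", "A3"))

  X <- stats::model.matrix(lm_used) * sqrt(w)
  cond <- tryCatch(kappa(X, exact = TRUE), error = function(e) NA_real_)

  pred <- stats::fitted(lm_used)
  if (any(pred <= 0)) {
    warning("fitted Kc/R_theta is non-positive inside the data range",
            call. = FALSE)
  }
  out <- structure(list(
    Mw_app = 1 / inv_Mw,
    A2 = A2,
    A3 = A3,
    se = sqrt(diag(Vp)),
    covariance = Vp,
    fit_rss = sum(w * stats::resid(lm_used)^2),
    order = use_order,
    c_range = range(c_gml),
    condition_number = cond,
    temperature = attr(series, "temperature"),
    n = length(y)
  ), class = "virial_fit")
  out
}

#' Predicted Kc/R_theta of a virial fit
#'
#' @param object a [fit_virial()] result.
#' @param c_gml mass concentrations in g/ml.
#' @param ... unused.
#' @return predicted Kc/R_theta (mol/g) at `c_gml`.
#' @export
predict.virial_fit <- function(object, c_gml, ...) {
  .check_positive(c_gml)
  1 / object$Mw_app + 2 * object$A2 * c_gml + 3 * object$A3 * c_gml^2
}

#' @export
print.virial_fit <- function(x, ...) {
  cat("<virial_fit> osmotic virial expansion, order", x$order, "\n")
  cat(sprintf("  Mw_app = %.4g g/mol (se %.2g)\n", x$Mw_app, x$se[["Mw_app"]]))
  cat(sprintf("  A2     = %.4g mol ml g^-2 (se %.2g)\n", x$A2, x$se[["A2"]]))
  if (x$order == 3L) {
    cat(sprintf("  A3     = %.4g mol ml^2 g^-3 (se %.2g)\n", x$A3, x$se[["A3"]]))
  }
  cat(sprintf("  n = %d, weighted RSS = %.3g, design condition = %.3g\n",
              x$n, x$fit_rss, x$condition_number))
  invisible(x)
}

#' Osmotic pressure derivative from a virial fit
#'
#' Evaluates `dPi/dc = RT * (Kc/R_theta)(c)`: the Debye ratio is the inverse
#' osmotic compressibility `(1/RT) dPi/dc`. With `c` in g/ml and Kc/R_theta in
#' mol/g the result is in J/g, i.e. Pa per (g m^-3) of concentration.
#'
#' @param fit a [fit_virial()] result.
#' @param c mass concentration(s) in g/ml, > 0.
#' @param temperature temperature in K; defaults to the temperature recorded
#'   on the fitted series.
#' @return dPi/dc in J/g at each `c`. Concentrations outside the fitted range
#'   are allowed but flagged with a warning (extrapolation).
#' @export
osmotic_pressure_derivative <- function(fit, c, temperature = fit$temperature) {
  .check_positive(c, temperature)
  if (any(c < fit$c_range[1L] | c > fit$c_range[2L])) {
    warning("concentration outside the fitted range: extrapolating the virial fit",
            call. = FALSE)
  }
  R_GAS * temperature * predict(fit, c)
}

#' Per-molecule excess free energy between two concentrations
#'
#' Integrates the fitted inverse osmotic compressibility to the free-energy
#' difference per solute molecule between a low and a high concentration.
#' Writing the per-molecule chemical-potential increment as
#' `d(mu) = (1/rho_N) dPi` with number density `rho_N = c N_A / M`, and using
#' `dPi/dc = RT (Kc/R_theta)`, gives
#' \deqn{\Delta g = \frac{M R T}{N_A}\int_{c_L}^{c_H}
#'       \frac{(Kc/R_\theta)(c)}{c}\, dc,}
#' which for the virial expansion has the closed form
#' \deqn{\Delta g = \frac{M R T}{N_A}\left[\frac{1}{M_w}\ln\frac{c_H}{c_L}
#'       + 2A_2(c_H - c_L) + \tfrac{3}{2}A_3(c_H^2 - c_L^2)\right].}
#' In the ideal dilute limit (A2 = A3 = 0, Mw = M) this reduces to
#' `kB T ln(cH/cL)`, the ideal chemical-potential difference.
#'
#' @param fit a [fit_virial()] result.
#' @param c_L,c_H lower and upper mass concentrations in g/ml, `0 < c_L <= c_H`.
#' @param molar_mass solute molar mass M in g/mol.
#' @param temperature temperature in K; defaults to the fitted series'.
#' @param method `"closed_form"` (default) or `"quadrature"` (adaptive
#'   numerical integration; agrees with the closed form to ~1e-8 relative,
#'   exercised by the test suite).
#' @return Delta g per molecule in J, with attribute `"kBT"` giving the same
#'   value in units of kB*T.
#' @export
#' @examples
#' s <- gen_sls(generator_config(seed = 1, noise_sls = 0))
#' f <- fit_virial(s)
#' free_energy_excess(f, 0.01, 0.09, molar_mass = 193.25, temperature = 298.15)
free_energy_excess <- function(fit, c_L, c_H, molar_mass,
                               temperature = fit$temperature,
                               method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  .check_positive(molar_mass, temperature)
  if (!is.numeric(c_L) || !is.numeric(c_H) || anyNA(c_L) || anyNA(c_H)) {
    stop("'c_L' and 'c_H' must be numeric", call. = FALSE)
  }
  if (any(c_L <= 0)) {
    stop("divergent integral: 'c_L' must be > 0 (the ideal term diverges at c = 0)",
         call. = FALSE)
  }
  if (any(c_H < c_L)) {
    stop("'c_L' must not exceed 'c_H'", call. = FALSE)
  }
  scale <- molar_mass * R_GAS * temperature / N_AVOGADRO
  if (method == "closed_form") {
    val <- scale * ((1 / fit$Mw_app) * log(c_H / c_L) +
                      2 * fit$A2 * (c_H - c_L) +
                      1.5 * fit$A3 * (c_H^2 - c_L^2))
  } else {
    integrand <- function(cc) predict(fit, cc) / cc
    val <- mapply(function(a, b) {
      if (a == b) return(0)
      stats::integrate(integrand, a, b, rel.tol = 1e-10)$value
    }, c_L, c_H) * scale
  }
  structure(val, kBT = val / (kB * temperature))
}

#' Excess free-energy curve on a concentration grid
#'
#' Evaluates [free_energy_excess()] from a reference concentration to every
#' point of a grid, the per-molecule free-energy curve of the solution.
#'
#' @param fit a [fit_virial()] result.
#' @param c_grid mass concentrations in g/ml, strictly positive increasing.
#' @param reference_c lower integration limit `c_L` in g/ml; defaults to the
#'   first grid point. `dg` is zero there by construction.
#' @inheritParams free_energy_excess
#' @return A data frame of class `free_energy_curve` with columns `c` (g/ml),
#'   `dg_J` and `dg_kBT`, and attribute `reference_c`.
#' @export
free_energy_curve <- function(fit, c_grid, molar_mass,
                              temperature = fit$temperature,
                              reference_c = c_grid[1L]) {
  .check_positive(c_grid, reference_c)
  if (any(diff(c_grid) <= 0)) {
    stop("'c_grid' must be strictly increasing", call. = FALSE)
  }
  if (any(c_grid < reference_c)) {
    stop("'c_grid' must not extend below 'reference_c'", call. = FALSE)
  }
  dg <- free_energy_excess(fit, reference_c, c_grid, molar_mass, temperature)
  structure(data.frame(c = c_grid, dg_J = as.numeric(dg),
                       dg_kBT = attr(dg, "kBT")),
            reference_c = reference_c,
            class = c("free_energy_curve", "data.frame"))
}
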
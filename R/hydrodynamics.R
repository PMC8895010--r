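#' DOSY gradient-attenuation experiment
#'
#' Container for a pulsed-field-gradient (Stejskal-Tanner) attenuation
#' series: signal intensity vs gradient strength together with the pulse
#' parameters that set the diffusion-encoding factor
#' `b(g) = gamma^2 g^2 delta^2 (Delta - delta/3)`.
#'
#' @param gradient_strengths gradient strengths g in T/m, nonnegative and
#'   increasing; must include g = 0.
#' @param intensities positive signal intensities (arbitrary units).
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1 (default 1H).
#' @param delta_little gradient pulse duration delta in s.
#' @param delta_big diffusion delay Delta in s; must exceed `delta_little/3`.
#' @return An object of class `dosy_experiment`.
#' @export
dosy_experiment <- function(gradient_strengths, intensities,
                            gamma = 2.675221874e8,
                            delta_little = 2e-3, delta_big = 0.05) {
  .check_positive(intensities, gamma, delta_little, delta_big)
  .check_nonnegative(gradient_strengths)
  if (length(gradient_strengths) != length(intensities)) {
    stop("gradient and intensity vectors must match in length", call. = FALSE)
  }
  if (any(diff(gradient_strengths) <= 0)) {
    stop("gradient strengths must be strictly increasing", call. = FALSE)
  }
  if (delta_big <= delta_little / 3) {
    stop("'delta_big' must exceed delta_little/3 for a positive encoding factor",
         call. = FALSE)
  }
  structure(list(gradient_strengths = as.numeric(gradient_strengths),
                 intensities = as.numeric(intensities),
                 gamma = gamma, delta_little = delta_little,
                 delta_big = delta_big),
            class = "dosy_experiment")
}

# Stejskal-Tanner diffusion-encoding factor b(g) [s m^-2]
.st_bfactor <- function(experiment) {
  experiment$gamma^2 * experiment$gradient_strengths^2 *
    experiment$delta_little^2 *
    (experiment$delta_big - experiment$delta_little / 3)
}

#' Fit a diffusion coefficient to DOSY attenuation data
#'
#' Fits the single-component Stejskal-Tanner decay
#' \deqn{I(g) = I_0 \exp[-D\,\gamma^2 g^2 \delta^2(\Delta - \delta/3)]}
#' by nonlinear least squares, seeded by linear regression of `log I` on the
#' encoding factor `b(g)` (for noiseless data the log-transformed problem is
#' exactly linear with slope `-D`). `D` is constrained positive; a fit pushed
#' to the boundary raises a warning.
#'
#' @param experiment a [dosy_experiment()]; at least 5 gradient points
#'   including g = 0.
#' @return An object of class `dosy_fit`: list with `D` (m^2/s), `D_se`,
#'   `I0`, `I0_se`, `residuals`, `fitted`, `r_squared`, `converged`.
#' @export
#' @examples
#' d <- gen_dosy(generator_config(seed = 7))
#' fit_dosy(d)$D
fit_dosy <- function(experiment) {
  if (!inherits(experiment, "dosy_experiment")) {
    stop("'experiment' must be a dosy_experiment", call. = FALSE)
  }
  if (length(experiment$gradient_strengths) < 5L) {
    stop("need at least 5 gradient points", call. = FALSE)
  }
  if (experiment$gradient_strengths[1L] != 0) {
    stop("the gradient list must include g = 0 (reference intensity)",
         call. = FALSE)
  }
  b <- .st_bfactor(experiment)
  I <- experiment$intensities
  # gross non-monotonicity: attenuation should not grow with b beyond noise
  if (stats::cor(b, I, method = "spearman") > 0.5) {
    stop("intensities increase with gradient strength: not a diffusion decay",
         call. = FALSE)
  }
  lin <- stats::lm(log(I) ~ b)
  D0 <- max(-stats::coef(lin)[[2L]], 1e-16)
  I00 <- exp(stats::coef(lin)[[1L]])
  fit <- minpack.lm::nlsLM(
    I ~ I0 * exp(-D * b),
    start = list(I0 = I00, D = D0),
    lower = c(I0 = 0, D = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(I0 = NA_real_, D = NA_real_))
  if (cf[["D"]] <= 0) {
    warning("fitted D pinned at the positivity bound; data carry no decay",
            call. = FALSE)
  }
  res <- stats::resid(fit)
  structure(list(D = cf[["D"]], D_se = se[["D"]],
                 I0 = cf[["I0"]], I0_se = se[["I0"]],
                 residuals = as.numeric(res),
                 fitted = as.numeric(stats::fitted(fit)),
                 r_squared = 1 - sum(res^2) / sum((I - mean(I))^2),
                 converged = isTRUE(fit$convInfo$isConv)),
            class = "dosy_fit")
}

#' @export
print.dosy_fit <- function(x, ...) {
  cat(sprintf("<dosy_fit> D = %.4g m^2/s (se %.2g), R^2 = %.4f\n",
              x$D, x$D_se, x$r_squared))
  invisible(x)
}

#' Stokes-Einstein relation: radius from diffusion coefficient
#'
#' `r_H = kB T / (6 pi eta D)`; the relation is its own inverse, so the same
#' formula maps a hydrodynamic radius back to a diffusion coefficient
#' ([stokes_einstein_diffusion()]).
#'
#' @param D diffusion coefficient in m^2/s.
#' @param temperature temperature in K.
#' @param eta solvent viscosity in Pa s.
#' @return hydrodynamic radius in m.
#' @export
#' @examples
#' stokes_einstein_radius(4e-11, 298.15, 0.544e-3)
stokes_einstein_radius <- function(D, temperature, eta) {
  .check_positive(D, temperature, eta)
  kB * temperature / (6 * pi * eta * D)
}

#' Stokes-Einstein relation: diffusion coefficient from radius
#'
#' @param r_H hydrodynamic radius in m.
#' @inheritParams stokes_einstein_radius
#' @return diffusion coefficient in m^2/s.
#' @export
stokes_einstein_diffusion <- function(r_H, temperature, eta) {
  .check_positive(r_H, temperature, eta)
  kB * temperature / (6 * pi * eta * r_H)
}

#' Scale a diffusion coefficient between species by inverse radius
#'
#' Under Stokes-Einstein hydrodynamics, diffusion coefficients are inversely
#' proportional to the hydrodynamic radius, so
#' `D_target = D_ref * r_ref / r_target`. This is how the dimer coefficient
#' is obtained from the measured monomer coefficient and the two hydrodynamic
#' radii.
#'
#' @param D_ref reference diffusion coefficient in m^2/s.
#' @param r_ref,r_target reference and target hydrodynamic radii in m.
#' @return scaled diffusion coefficient in m^2/s.
#' @export
#' @examples
#' scale_diffusion(4e-11, 3.72e-10, 4.65e-10)  # monomer -> dimer
scale_diffusion <- function(D_ref, r_ref, r_target) {
  .check_positive(D_ref, r_ref, r_target)
  D_ref * r_ref / r_target
}

#' Bundle of monomer/dimer transport parameters
#'
#' Holds the diffusion coefficients and hydrodynamic radii of both species
#' and enforces Stokes-Einstein consistency `D1 r1 = D2 r2` at construction
#' (to 1e-9 relative) when all four are supplied; with one of `D2`/`r2`
#' missing it is completed from the inverse-radius scaling.
#'
#' @param D1 monomer diffusion coefficient, m^2/s.
#' @param r1 monomer hydrodynamic radius, m.
#' @param D2 dimer diffusion coefficient, m^2/s (optional if `r2` given).
#' @param r2 dimer hydrodynamic radius, m (optional if `D2` given).
#' @param temperature temperature in K.
#' @param eta solvent viscosity in Pa s (optional metadata).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D1, r1, D2 = NULL, r2 = NULL,
                             temperature = 298.15, eta = NA_real_) {
  .check_positive(D1, r1, temperature)
  if (is.null(D2) && is.null(r2)) {
    stop("supply at least one of 'D2' or 'r2'", call. = FALSE)
  }
  if (is.null(D2)) D2 <- scale_diffusion(D1, r1, r2)
  if (is.null(r2)) r2 <- r1 * D1 / D2
  .check_positive(D2, r2)
  if (abs(D1 * r1 - D2 * r2) > 1e-9 * D1 * r1) {
    stop("Stokes-Einstein inconsistency: D1*r1 and D2*r2 differ by more than ",
         "1e-9 relative", call. = FALSE)
  }
  structure(list(D1 = D1, D2 = D2, r1 = r1, r2 = r2,
                 temperature = temperature, eta = eta),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("<diffusion_params>\n")
  cat(sprintf("  monomer: D1 = %.4g m^2/s, r1 = %.3g m\n", x$D1, x$r1))
  cat(sprintf("  dimer:   D2 = %.4g m^2/s, r2 = %.3g m\n", x$D2, x$r2))
  invisible(x)
}
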
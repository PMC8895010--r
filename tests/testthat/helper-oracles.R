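# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: root bracketing instead of the closed form,
# finite differences instead of analytic derivatives, and a direct
# finite-difference boundary-value solve instead of the matched analytic
# profile.

# Thomas algorithm for a tridiagonal system (lower/main/upper diagonals)
.thomas_solve <- function(lower, main, upper, rhs) {
  n <- length(main)
  for (i in 2:n) {
    w <- lower[i - 1L] / main[i - 1L]
    main[i] <- main[i] - w * upper[i - 1L]
    rhs[i] <- rhs[i] - w * rhs[i - 1L]
  }
  x <- numeric(n)
  x[n] <- rhs[n] / main[n]
  for (i in (n - 1L):1L) x[i] <- (rhs[i] - upper[i] * x[i + 1L]) / main[i]
  x
}

# monomer concentration by root bracketing of the mass balance
# c = [M] + 2 k_D [M]^2
speciate_bisect <- function(k_D, c_total) {
  if (c_total == 0) return(list(monomer = 0, dimer = 0))
  M <- stats::uniroot(function(m) m + 2 * k_D * m^2 - c_total,
                      c(0, c_total), tol = 1e-15)$root
  list(monomer = M, dimer = k_D * M^2)
}

# finite-difference solve of the screened spherical problem
#   D2 (delta2'' + 2/r delta2') - k2 delta2 + s * 1[r < R] = 0
# via u = r * delta2 (so D2 u'' - k2 u = -s r inside, 0 outside),
# u(0) = 0, u(rmax) = 0, with the source amplitude s fixed by linearity so
# that delta2(0) = contrast * n2_inf. Returns delta2 on the interior nodes.
bvp_screened_profile <- function(D2, k2, R, contrast, n2_inf,
                                 rmax = NULL, n = 8000L) {
  lambda <- sqrt(D2 / k2)
  if (is.null(rmax)) rmax <- 14 * lambda
  h <- rmax / (n + 1)
  r <- h * seq_len(n)
  main <- rep(-2 * D2 / h^2 - k2, n)
  off <- rep(D2 / h^2, n - 1)
  rhs_unit <- ifelse(r < R, -r, 0)          # unit source amplitude
  u1 <- .thomas_solve(off, main, off, rhs_unit)
  d2_unit <- u1 / r
  # central value by linear extrapolation of u/r toward r = 0 (the profile
  # is even in r, so the extrapolation error is O(h^2))
  centre_unit <- d2_unit[1L] +
    (d2_unit[1L] - d2_unit[2L]) * r[1L] / (r[2L] - r[1L])
  s <- contrast * n2_inf / centre_unit
  list(r = r, delta2 = s * d2_unit, lambda = lambda)
}

# default reaction-diffusion parameter bundle at the 0.5 M study condition
default_rd_params <- function(conc_M = 0.5, k_D = 1.147,
                              k2 = 1.25e5, D1 = 4e-11, D2 = 3.2e-11) {
  sp <- speciate(k_D, conc_M)
  rd_params(k2 = k2, D1 = D1, D2 = D2,
            n1_inf = molar_to_number_density(sp$monomer),
            n2_inf = molar_to_number_density(sp$dimer))
}
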
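#' Physical constants (SI, 2019 redefinition)
#'
#' Exact CODATA values used throughout the package: Boltzmann constant
#' `kB` (J K^-1), Avogadro number `N_AVOGADRO` (mol^-1) and the molar gas
#' constant `R_GAS` (J mol^-1 K^-1).
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
kB <- 1.380649e-23

#' @rdname constants
#' @export
N_AVOGADRO <- 6.02214076e23

#' @rdname constants
#' @export
R_GAS <- 1.380649e-23 * 6.02214076e23

.check_positive <- function(..., .names = NULL) {
  vals <- list(...)
  nm <- if (is.null(.names)) {
    vapply(substitute(list(...))[-1L], deparse, character(1))
  } else {
    .names
  }
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) == 0L || anyNA(v) || any(v <= 0)) {
      stop(sprintf("'%s' must be strictly positive and finite", nm[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# noiseless synthetic data produce legitimately perfect linear fits; the
# stats warnings about unreliable summaries are expected there, and the
# near-zero standard errors they caution about are exactly what we report
.quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

.check_nonnegative <- function(..., .names = NULL) {
  vals <- list(...)
  nm <- if (is.null(.names)) {
    vapply(substitute(list(...))[-1L], deparse, character(1))
  } else {
    .names
  }
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) == 0L || anyNA(v) || any(v < 0)) {
      stop(sprintf("'%s' must be nonnegative and finite", nm[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
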
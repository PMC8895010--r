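#' Concentration series container
#'
#' Paired (concentration, observable) measurements with declared units, the
#' common currency of the fitting stages: Debye-plot series (Kc/R_theta vs
#' mass concentration), chemical-shift dilution series (ppm vs molar
#' concentration), and anything of the same shape.
#'
#' @param concentration numeric vector, strictly positive and strictly
#'   increasing.
#' @param value observable at each concentration (same length).
#' @param sigma optional per-point standard uncertainty of `value` (same
#'   length, positive). Used as weights `1/sigma^2` by the fitters.
#' @param unit concentration unit, one of `"mg_per_ml"`, `"g_per_ml"`, `"M"`.
#' @param temperature temperature in K (scalar, optional metadata).
#' @param label optional series label (e.g. a carbon assignment).
#'
#' @return An object of class `concentration_series`: a data frame with
#'   columns `concentration`, `value` (and `sigma` when given) and attributes
#'   `unit`, `temperature`, `label`.
#' @export
#' @examples
#' s <- concentration_series(c(10, 20, 40), c(1.2e-5, 1.3e-5, 1.5e-5),
#'                           unit = "mg_per_ml", temperature = 298.15)
#' conc_in(s, "g_per_ml")
concentration_series <- function(concentration, value, sigma = NULL,
                                 unit = c("mg_per_ml", "g_per_ml", "M"),
                                 temperature = NA_real_, label = NULL) {
  unit <- match.arg(unit)
  concentration <- as.numeric(concentration)
  value <- as.numeric(value)
  if (length(concentration) != length(value)) {
    stop("'concentration' and 'value' must have the same length", call. = FALSE)
  }
  if (anyNA(concentration) || any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (any(diff(concentration) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (anyNA(value)) stop("'value' must not contain NA", call. = FALSE)
  out <- data.frame(concentration = concentration, value = value)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(value) || anyNA(sigma) || any(sigma <= 0)) {
      stop("'sigma' must be positive and match 'value' in length", call. = FALSE)
    }
    out$sigma <- sigma
  }
  structure(out,
            unit = unit,
            temperature = as.numeric(temperature)[1L],
            label = label,
            class = c("concentration_series", "data.frame"))
}

# pairwise conversion factors to g/ml for the mass units
.MASS_UNIT_TO_G_PER_ML <- c(mg_per_ml = 1e-3, g_per_ml = 1)

#' Concentrations of a series in a requested unit
#'
#' Mass units interconvert directly; conversion between mass and molar units
#' requires the solute molar mass `M` in g/mol (1 M = M g/l = M/1000 g/ml).
#'
#' @param series a [concentration_series()].
#' @param unit target unit, `"mg_per_ml"`, `"g_per_ml"` or `"M"`.
#' @param molar_mass solute molar mass in g/mol; required when converting
#'   between mass and molar units.
#' @return numeric vector of concentrations in `unit`.
#' @export
conc_in <- function(series, unit = c("g_per_ml", "mg_per_ml", "M"),
                    molar_mass = NULL) {
  unit <- match.arg(unit)
  from <- attr(series, "unit")
  x <- series$concentration
  if (from == unit) return(x)
  mass_units <- names(.MASS_UNIT_TO_G_PER_ML)
  if (from %in% mass_units && unit %in% mass_units) {
    return(x * .MASS_UNIT_TO_G_PER_ML[[from]] / .MASS_UNIT_TO_G_PER_ML[[unit]])
  }
  if (is.null(molar_mass)) {
    stop("'molar_mass' [g/mol] is required to convert between mass and molar units",
         call. = FALSE)
  }
  .check_positive(molar_mass)
  if (from %in% mass_units) {            # mass -> molar
    g_ml <- x * .MASS_UNIT_TO_G_PER_ML[[from]]
    g_ml * 1000 / molar_mass             # g/ml -> g/l -> mol/l
  } else {                               # molar -> mass
    g_ml <- x * molar_mass / 1000
    g_ml / .MASS_UNIT_TO_G_PER_ML[[unit]]
  }
}

#' @export
print.concentration_series <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<concentration_series> %d points, unit = %s%s\n",
              nrow(x), attr(x, "unit"),
              if (is.null(lab)) "" else paste0(", label = ", lab)))
  if (!is.na(attr(x, "temperature"))) {
    cat(sprintf("  temperature: %.2f K\n", attr(x, "temperature")))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
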
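#' Pipeline configuration
#'
#' Validated key-value configuration for the end-to-end derived-constant
#' chain ([run_paper_chain()]). Unknown keys are rejected; all values are
#' checked for sign and plausibility at load time (no silent unit coercion).
#'
#' @param temperature temperature, K.
#' @param molar_mass solute molar mass, g/mol (default 193.25, the C14H11N
#'   model compound).
#' @param viscosity solvent viscosity, Pa s (methanol near room temperature).
#' @param cluster_size mean cluster size, m, interpreted as a diameter
#'   (default 32 nm).
#' @param D1 monomer diffusion coefficient, m^2/s.
#' @param r1,r2 monomer and dimer hydrodynamic radii, m.
#' @param k_D dimerization constant, 1/M.
#' @param conc_M total solute concentration for the speciation report, M.
#' @param drive,shrink radius-dynamics coefficients (see [radius_model()]).
#' @param R0 initial cluster radius for the trajectory, m.
#' @param t_end trajectory end time, s.
#' @param core_contrast dimer core contrast for the profile stage.
#' @param ... rejected; a typo in a key name is an error, not a default.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(temperature = 298.15,
                            molar_mass = 193.25,
                            viscosity = 0.544e-3,
                            cluster_size = 3.2e-8,
                            D1 = 4e-11,
                            r1 = 3.72e-10,
                            r2 = 4.65e-10,
                            k_D = 1.147,
                            conc_M = 0.5,
                            drive = 1 / 3,
                            shrink = 1,
                            R0 = 1e-9,
                            t_end = 1e-3,
                            core_contrast = 10,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  .check_positive(temperature, molar_mass, viscosity, cluster_size,
                  D1, r1, r2, conc_M, R0, t_end)
  .check_nonnegative(k_D, drive, shrink, core_contrast)
  structure(list(temperature = temperature, molar_mass = molar_mass,
                 viscosity = viscosity, cluster_size = cluster_size,
                 D1 = D1, r1 = r1, r2 = r2, k_D = k_D, conc_M = conc_M,
                 drive = drive, shrink = shrink, R0 = R0, t_end = t_end,
                 core_contrast = core_contrast),
            class = "pipeline_config")
}

#' Run the derived-constant cascade
#'
#' Executes the full chain that links the measured constants: the dimer
#' diffusion coefficient from inverse-radius scaling (`D2 = D1 r1/r2`), the
#' dimer decay rate from the cluster radius (`k2 = D2/(cluster_size/2)^2`),
#' the screening length `Lambda = sqrt(D2/k2)`, the steady cluster radius
#' `R*` and time-to-plateau `t_99` of the radius dynamics, and the
#' monomer/dimer speciation at the requested concentration. Every entry is
#' computed by the corresponding stage function, so the report agrees
#' bit-for-bit with stage-by-stage calls.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `paper_chain`: list of named entries, each a
#'   list with `value`, `unit` and `provenance` (which stage produced it),
#'   plus the `config` used.
#' @export
#' @examples
#' chain <- run_paper_chain(pipeline_config())
#' chain$k2$value  # 1.25e5
run_paper_chain <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  D2 <- scale_diffusion(config$D1, config$r1, config$r2)
  R_cluster <- config$cluster_size / 2
  k2 <- decay_rate_from_radius(D2, R_cluster)
  lambda <- screening_length(D2, k2)
  model <- radius_model(D2 = D2, k2 = k2, drive = config$drive,
                        shrink = config$shrink)
  Rstar <- steady_radius(model)
  traj <- integrate_radius(config$R0, model, config$t_end)
  sp <- speciate(config$k_D, config$conc_M)
  entry <- function(value, unit, provenance) {
    list(value = value, unit = unit, provenance = provenance)
  }
  structure(list(
    D2 = entry(D2, "m^2/s", "scale_diffusion(D1, r1, r2)"),
    k2 = entry(k2, "1/s", "decay_rate_from_radius(D2, cluster_size/2)"),
    lambda_screen = entry(lambda, "m", "screening_length(D2, k2)"),
    R_steady = entry(Rstar, "m", "steady_radius(radius_model)"),
    t_99 = entry(attr(traj, "t_99"), "s", "integrate_radius(R0, model, t_end)"),
    monomer = entry(sp$monomer, "M", "speciate(k_D, conc_M)"),
    dimer = entry(sp$dimer, "M", "speciate(k_D, conc_M)"),
    frac_molecules_in_dimers = entry(sp$frac_molecules_in_dimers, "",
                                     "speciate(k_D, conc_M)"),
    config = config
  ), class = "paper_chain")
}

#' @export
print.paper_chain <- function(x, ...) {
  cat("<paper_chain> derived-constant cascade\n")
  for (nm in setdiff(names(x), "config")) {
    e <- x[[nm]]
    cat(sprintf("  %-26s %.6g %s   [%s]\n", nm, e$value, e$unit, e$provenance))
  }
  invisible(x)
}

#' Write a structured report to JSON
#'
#' Serializes a [run_paper_chain()] report (or any named list of
#' value/unit/provenance entries) to pretty-printed JSON with full numeric
#' precision.
#'
#' @param report a `paper_chain` or named list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "paper_chain")) {
    report <- report[setdiff(names(report), "config")]
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- CSV schema I/O ---------------------------------------------------------

.read_csv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c(required, optional), names(df))) {
    if (col == "carbon") next
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1L]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Read a static-light-scattering CSV
#'
#' Expected header: `conc_mg_per_ml, kc_over_r` and optionally `sigma`.
#'
#' @param path CSV file path.
#' @param temperature temperature in K recorded on the series.
#' @return a [concentration_series()] (mg/ml).
#' @export
read_sls_csv <- function(path, temperature = 298.15) {
  df <- .read_csv_checked(path, c("conc_mg_per_ml", "kc_over_r"), "sigma")
  concentration_series(df$conc_mg_per_ml, df$kc_over_r,
                       sigma = df$sigma, unit = "mg_per_ml",
                       temperature = temperature)
}

#' Read a long-format chemical-shift CSV
#'
#' Expected header: `carbon, conc_M, shift_ppm` and optionally `sigma`.
#'
#' @param path CSV file path.
#' @return named list of [concentration_series()] (unit `"M"`), one per
#'   carbon, suitable for [fit_dimerization()].
#' @export
read_shifts_csv <- function(path) {
  df <- .read_csv_checked(path, c("carbon", "conc_M", "shift_ppm"), "sigma")
  out <- lapply(split(df, df$carbon), function(d) {
    d <- d[order(d$conc_M), ]
    concentration_series(d$conc_M, d$shift_ppm, sigma = d$sigma,
                         unit = "M", label = d$carbon[1L])
  })
  out[unique(df$carbon)]
}

#' Read a DOSY attenuation CSV
#'
#' Expected header: `gradient_T_per_m, intensity`; the pulse parameters are
#' not part of the file and must be supplied.
#'
#' @param path CSV file path.
#' @inheritParams dosy_experiment
#' @return a [dosy_experiment()].
#' @export
read_dosy_csv <- function(path, gamma = 2.675221874e8,
                          delta_little = 2e-3, delta_big = 0.05) {
  df <- .read_csv_checked(path, c("gradient_T_per_m", "intensity"))
  dosy_experiment(df$gradient_T_per_m, df$intensity, gamma = gamma,
                  delta_little = delta_little, delta_big = delta_big)
}

#' Write a concentration series (or series list) to CSV
#'
#' Inverse of the readers: SLS series write `conc_mg_per_ml, kc_over_r[,
#' sigma]`; molar shift series (single or list) write long-format
#' `carbon, conc_M, shift_ppm[, sigma]`. Round-tripping preserves values to
#' full double precision.
#'
#' @param x a [concentration_series()] or named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  if (inherits(x, "concentration_series")) {
    if (attr(x, "unit") == "M") {
      x <- stats::setNames(list(x), attr(x, "label") %||% "C1")
    } else {
      df <- data.frame(conc_mg_per_ml = fmt(conc_in(x, "mg_per_ml")),
                       kc_over_r = fmt(x$value))
      if (!is.null(x$sigma)) df$sigma <- fmt(x$sigma)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      return(invisible(path))
    }
  }
  rows <- lapply(names(x), function(nm) {
    s <- x[[nm]]
    d <- data.frame(carbon = nm, conc_M = fmt(s$concentration),
                    shift_ppm = fmt(s$value))
    if (!is.null(s$sigma)) d$sigma <- fmt(s$sigma)
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
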
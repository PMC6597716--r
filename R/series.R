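#' A single initial-velocity titration
#'
#' One enzyme at one temperature, with one ligand varied while the other is
#' held fixed; the raw material for a Michaelis-Menten fit.
#'
#' @param enzyme enzyme label.
#' @param temperature_C assay temperature, degrees C.
#' @param varied_ligand label of the varied ligand ("NAD" or "D-3-IPM").
#' @param fixed_conc concentration of the non-varied ligand, mol/L.
#' @param conc varied-ligand concentrations, mol/L (strictly positive).
#' @param velocity initial velocities, mol/L/s.
#' @param enzyme_conc active-site concentration, mol/L.
#' @param truth optional [enzyme_truth()] the series was simulated from,
#'   retained for parameter-recovery tests.
#' @return an object of class `kinetic_series`.
#' @export
kinetic_series <- function(enzyme, temperature_C, varied_ligand,
                           conc, velocity, enzyme_conc,
                           fixed_conc = NA_real_, truth = NULL) {
  stopifnot(length(conc) == length(velocity), length(conc) >= 1,
            all(conc > 0), enzyme_conc > 0)
  structure(
    list(enzyme = enzyme, temperature_C = temperature_C,
         varied_ligand = varied_ligand, fixed_conc = fixed_conc,
         points = data.frame(conc = as.numeric(conc),
                             velocity = as.numeric(velocity)),
         enzyme_conc = enzyme_conc, truth = truth),
    class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("Kinetic series: %s at %g C, varied %s (%d points)\n",
              x$enzyme, x$temperature_C, x$varied_ligand, nrow(x$points)))
  print(utils::head(x$points, 6))
  if (nrow(x$points) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.kinetic_series <- function(x, ...) {
  data.frame(enzyme = x$enzyme, temperature_C = x$temperature_C,
             ligand = x$varied_ligand, conc_M = x$points$conc,
             enzyme_conc_M = x$enzyme_conc,
             velocity_per_s = x$points$velocity)
}

#' Write / read a kinetic series as CSV
#'
#' Columns: `enzyme, temperature_C, ligand, conc_M, enzyme_conc_M,
#' velocity_per_s`.
#'
#' @param x a `kinetic_series`.
#' @param path file path.
#' @return `write_kinetic_series` returns `path` invisibly;
#'   `read_kinetic_series` returns a `kinetic_series`.
#' @export
write_kinetic_series <- function(x, path) {
  stopifnot(inherits(x, "kinetic_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_series
#' @export
read_kinetic_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "temperature_C", "ligand", "conc_M",
            "enzyme_conc_M", "velocity_per_s")
  if (!all(need %in% names(df)))
    stop("kinetic series CSV must have columns: ",
         paste(need, collapse = ", "))
  kinetic_series(enzyme = df$enzyme[1], temperature_C = df$temperature_C[1],
                 varied_ligand = df$ligand[1], conc = df$conc_M,
                 velocity = df$velocity_per_s,
                 enzyme_conc = df$enzyme_conc_M[1])
}

#' A thermal melt curve
#'
#' Ellipticity (mdeg, e.g. at 222 nm) versus temperature for one protein.
#'
#' @param temperature_C temperatures, degrees C, strictly increasing,
#'   at least 20 points.
#' @param ellipticity ellipticities, mdeg.
#' @param enzyme protein label.
#' @param scan_rate scan rate, degrees C per minute (metadata only).
#' @param truth optional [enzyme_truth()] the curve was simulated from.
#' @return an object of class `melt_curve`.
#' @export
melt_curve <- function(temperature_C, ellipticity, enzyme = "protein",
                       scan_rate = 1.0, truth = NULL) {
  stopifnot(length(temperature_C) == length(ellipticity),
            length(temperature_C) >= 20,
            all(diff(temperature_C) > 0))
  structure(
    list(points = data.frame(temperature_C = as.numeric(temperature_C),
                             ellipticity = as.numeric(ellipticity)),
         enzyme = enzyme, scan_rate = scan_rate, truth = truth),
    class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve: %s, %d points, %.1f-%.1f C (scan %.1f C/min)\n",
              x$enzyme, nrow(x$points), min(x$points$temperature_C),
              max(x$points$temperature_C), x$scan_rate))
  invisible(x)
}

#' Write / read a melt curve as two-column CSV
#'
#' Columns: `temperature_C, ellipticity_mdeg`.
#' @param x a `melt_curve`.
#' @param path file path.
#' @param enzyme label used when reading.
#' @export
write_melt_curve <- function(x, path) {
  stopifnot(inherits(x, "melt_curve"))
  utils::write.csv(
    data.frame(temperature_C = x$points$temperature_C,
               ellipticity_mdeg = x$points$ellipticity),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_curve
#' @export
read_melt_curve <- function(path, enzyme = "protein") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "ellipticity_mdeg") %in% names(df)))
    stop("melt curve CSV must have columns temperature_C, ellipticity_mdeg")
  melt_curve(df$temperature_C, df$ellipticity_mdeg, enzyme = enzyme)
}
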
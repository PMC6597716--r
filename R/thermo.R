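check_convention <- function(convention) {
  match.arg(convention, c("association", "as_printed"))
}

# R-squared without summary.lm's perfect-fit warning on noiseless data.
r_squared_ols <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Activation free energy from a turnover number
#'
#' Transition-state theory (Eyring):
#' `dG_act = -R T ln(kcat h / (k_B T))`, the free energy difference between
#' the Michaelis complex and the transition state.
#'
#' @param kcat turnover number, 1/s (> 0).
#' @param T_K temperature, Kelvin (> 0).
#' @param constants see [physical_constants()].
#' @return activation free energy, kJ/mol.
#' @export
#' @examples
#' eyring_dg_act(0.37, 298.15)  # ~75.5 kJ/mol
eyring_dg_act <- function(kcat, T_K, constants = physical_constants()) {
  if (any(kcat <= 0)) stop("kcat must be positive")
  if (any(T_K <= 0)) stop("temperature must be positive (Kelvin)")
  -constants$R * T_K * log(kcat * constants$h / (constants$k_B * T_K))
}

#' Binding free energy from a Michaelis constant
#'
#' The free energy change on ligand binding (initial state to Michaelis
#' complex), from `Km` non-dimensionalised by the 1 M standard state.
#' Under the default association convention,
#' `dG_m = R T ln(Km / c0)`: tight (sub-molar) binding is favourable,
#' dG_m < 0. `"as_printed"` returns the sign-flipped quantity
#' `-R T ln(Km / c0)`, the literal form sometimes printed in the enzymology
#' literature; see the package vignette for why the association convention
#' is the default.
#'
#' @param Km Michaelis constant, mol/L (> 0).
#' @param T_K temperature, Kelvin.
#' @param convention `"association"` (default) or `"as_printed"`.
#' @param constants see [physical_constants()].
#' @return binding free energy, kJ/mol.
#' @export
#' @examples
#' binding_dg(2.2e-6, 298.15)  # ~ -32.3 kJ/mol
binding_dg <- function(Km, T_K, convention = "association",
                       constants = physical_constants()) {
  convention <- check_convention(convention)
  if (any(Km <= 0)) stop("Km must be positive")
  if (any(T_K <= 0)) stop("temperature must be positive (Kelvin)")
  val <- constants$R * T_K * log(Km / constants$c_standard)
  if (convention == "as_printed") -val else val
}

#' Total barrier from initial state to transition state
#'
#' `dG_T = dG_act + dG_m`.
#' @param dG_act activation free energy, kJ/mol.
#' @param dG_m binding free energy, kJ/mol.
#' @return kJ/mol.
#' @export
dg_total <- function(dG_act, dG_m) dG_act + dG_m

#' Activation enthalpy from an Arrhenius regression
#'
#' Ordinary least squares of `ln kcat` on `1/T`;
#' `dH_act = -R * slope - R * T_ref`, with the `-RT` correction (from the
#' Eyring prefactor) evaluated at the reference temperature.
#'
#' @param series data frame with columns `T_K` (Kelvin) and `kcat` (1/s);
#'   3 or more distinct temperatures recommended, 2 allowed with a warning.
#' @param T_ref reference temperature, Kelvin (default 298.15).
#' @param constants see [physical_constants()].
#' @return list of class `arrhenius_fit`: `dH_act` (kJ/mol), `slope`,
#'   `intercept`, `r_squared`, `T_ref`.
#' @export
#' @examples
#' arrhenius_dh_act(data.frame(T_K = c(25, 40, 70) + 273.15,
#'                             kcat = c(0.37, 2.4, 79)))
arrhenius_dh_act <- function(series, T_ref = 298.15,
                             constants = physical_constants()) {
  stopifnot(all(c("T_K", "kcat") %in% names(series)))
  n <- length(unique(series$T_K))
  if (n < 2) stop("at least 2 distinct temperatures required")
  if (n == 2) warning("only 2 temperatures: slope has no degrees of freedom")
  if (any(series$kcat <= 0)) stop("kcat values must be positive")
  fit <- stats::lm(log(kcat) ~ I(1 / T_K), data = series)
  slope <- unname(stats::coef(fit)[2])
  structure(list(dH_act = -constants$R * slope - constants$R * T_ref,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r_squared_ols(fit),
                 T_ref = T_ref),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: dH_act = %.2f kJ/mol (slope %.1f K, r2 %.4f)\n",
              x$dH_act, x$slope, x$r_squared))
  invisible(x)
}

#' Binding enthalpy from a van't Hoff regression
#'
#' Ordinary least squares of `ln(Km/c0)` on `1/T`. Under the association
#' convention `dH_m = +R * slope` (exothermic binding of NAD-like cofactors
#' gives negative values and a Km that worsens with temperature);
#' `"as_printed"` returns `-R * slope`.
#'
#' @param series data frame with columns `T_K` (Kelvin) and `Km` (mol/L).
#' @param convention `"association"` (default) or `"as_printed"`.
#' @param constants see [physical_constants()].
#' @return list of class `vanthoff_fit`: `dH_m` (kJ/mol), `slope`,
#'   `intercept`, `r_squared`, `convention`.
#' @export
#' @examples
#' vanthoff_dhm(data.frame(T_K = c(25, 40, 70) + 273.15,
#'                         Km = c(2.2e-6, 12e-6, 210e-6)))
vanthoff_dhm <- function(series, convention = "association",
                         constants = physical_constants()) {
  stopifnot(all(c("T_K", "Km") %in% names(series)))
  convention <- check_convention(convention)
  n <- length(unique(series$T_K))
  if (n < 2) stop("at least 2 distinct temperatures required")
  if (n == 2) warning("only 2 temperatures: slope has no degrees of freedom")
  if (any(series$Km <= 0)) stop("Km values must be positive")
  df <- data.frame(T_K = series$T_K,
                   lnKm = log(series$Km / constants$c_standard))
  fit <- stats::lm(lnKm ~ I(1 / T_K), data = df)
  slope <- unname(stats::coef(fit)[2])
  dH <- constants$R * slope
  structure(list(dH_m = if (convention == "as_printed") -dH else dH,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r_squared_ols(fit),
                 convention = convention),
            class = "vanthoff_fit")
}

#' @export
print.vanthoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (%s): dH_m = %.2f kJ/mol (r2 %.4f)\n",
              x$convention, x$dH_m, x$r_squared))
  invisible(x)
}

#' Assemble a reaction-coordinate energy profile
#'
#' Combines the free energies at the reference temperature (from `kcat` and
#' `Km`) with the regression enthalpies into the nine state quantities of a
#' three-state profile (initial state IS, Michaelis complex MS, transition
#' state TS): dG, dH and -TdS for the binding step (`_m`), the activation
#' step (`_act`) and their total (`_T`). Entropies are obtained by
#' difference, `-TdS_X = dG_X - dH_X`, so the conservation identities
#' `dG_T = dG_act + dG_m` and `dH_T = dH_act + dH_m` hold by construction.
#'
#' @param kcat turnover number at `T_ref`, 1/s.
#' @param Km Michaelis constant at `T_ref`, mol/L.
#' @param dH_act activation enthalpy, kJ/mol ([arrhenius_dh_act()] result or
#'   number).
#' @param dH_m binding enthalpy, kJ/mol ([vanthoff_dhm()] result or number;
#'   its convention must match `convention`).
#' @param T_ref reference temperature, Kelvin.
#' @param enzyme label.
#' @param convention `"association"` (default) or `"as_printed"`.
#' @param constants see [physical_constants()].
#' @return object of class `thermo_profile`.
#' @export
assemble_profile <- function(kcat, Km, dH_act, dH_m, T_ref = 298.15,
                             enzyme = "enzyme", convention = "association",
                             constants = physical_constants()) {
  convention <- check_convention(convention)
  if (inherits(dH_act, "arrhenius_fit")) dH_act <- dH_act$dH_act
  if (inherits(dH_m, "vanthoff_fit")) {
    if (dH_m$convention != convention)
      stop("van't Hoff fit convention '", dH_m$convention,
           "' does not match profile convention '", convention, "'")
    dH_m <- dH_m$dH_m
  }
  dG_act <- eyring_dg_act(kcat, T_ref, constants)
  dG_m <- binding_dg(Km, T_ref, convention, constants)
  dG_T <- dg_total(dG_act, dG_m)
  dH_T <- dH_act + dH_m
  structure(
    list(enzyme = enzyme, T_ref = T_ref, convention = convention,
         dG_act = dG_act, dG_m = dG_m, dG_T = dG_T,
         dH_act = dH_act, dH_m = dH_m, dH_T = dH_T,
         mTdS_act = dG_act - dH_act,
         mTdS_m = dG_m - dH_m,
         mTdS_T = dG_T - dH_T),
    class = "thermo_profile")
}

profile_quantities <- c("dG_act", "dG_m", "dG_T",
                        "dH_act", "dH_m", "dH_T",
                        "mTdS_act", "mTdS_m", "mTdS_T")

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf("Thermodynamic profile: %s at %.2f K (%s convention)\n",
              x$enzyme, x$T_ref, x$convention))
  m <- matrix(unlist(x[profile_quantities]), nrow = 3, byrow = TRUE,
              dimnames = list(c("dG", "dH", "-TdS"),
                              c("activation", "binding (m)", "total (T)")))
  print(round(m[, c("binding (m)", "activation", "total (T)")], 1))
  invisible(x)
}

#' @export
coef.thermo_profile <- function(object, ...) {
  unlist(object[profile_quantities])
}

#' State levels of a profile relative to the initial state
#'
#' Returns the IS/MS/TS levels (initial state fixed at zero) for free
#' energy, enthalpy and entropy, the quantities plotted in a
#' reaction-coordinate diagram.
#'
#' @param profile a [assemble_profile()] result.
#' @return data frame with columns `state` (IS, MS, TS), `dG`, `dH`, `mTdS`.
#' @export
profile_states <- function(profile) {
  stopifnot(inherits(profile, "thermo_profile"))
  data.frame(state = c("IS", "MS", "TS"),
             dG = c(0, profile$dG_m, profile$dG_T),
             dH = c(0, profile$dH_m, profile$dH_T),
             mTdS = c(0, profile$mTdS_m, profile$mTdS_T))
}

#' @export
plot.thermo_profile <- function(x, which = "dG", ...) {
  st <- profile_states(x)
  graphics::plot(1:3, st[[which]], type = "b", xaxt = "n",
                 xlab = "reaction coordinate",
                 ylab = paste(which, "(kJ/mol)"),
                 main = x$enzyme, ...)
  graphics::axis(1, at = 1:3, labels = st$state)
  invisible(x)
}

#' Compare reaction-coordinate profiles
#'
#' Pairwise root-mean-square distance over the nine state quantities, plus a
#' nearest-reference classification: for each profile, which *other* profile
#' it most resembles. Used to ask whether an engineered mutant's energetics
#' pattern sits closer to the mesophilic or the thermophilic wild type.
#'
#' @param profiles list of [assemble_profile()] results sharing `T_ref` and
#'   convention.
#' @return list of class `profile_comparison`: `distance` (symmetric
#'   matrix), `nearest` (named character).
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, inherits, TRUE, "thermo_profile")))
  conv <- unique(vapply(profiles, `[[`, "", "convention"))
  tref <- unique(vapply(profiles, `[[`, 1, "T_ref"))
  if (length(conv) > 1) stop("profiles mix sign conventions")
  if (length(tref) > 1) stop("profiles mix reference temperatures")
  nm <- vapply(profiles, `[[`, "", "enzyme")
  q <- t(vapply(profiles, function(p) unlist(p[profile_quantities]),
                numeric(length(profile_quantities))))
  rownames(q) <- nm
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(mean((q[i, ] - q[j, ])^2))
  nearest <- vapply(seq_len(n), function(i) nm[-i][which.min(d[i, -i])], "")
  names(nearest) <- nm
  structure(list(distance = d, nearest = nearest, quantities = q),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("RMS distance between profiles (kJ/mol):\n")
  print(round(x$distance, 2))
  cat("nearest profile:\n")
  print(x$nearest)
  invisible(x)
}

#' Write a profile as JSON and its state levels as TSV
#' @param profile a `thermo_profile`.
#' @param json_path,tsv_path output paths.
#' @export
write_profile <- function(profile, json_path, tsv_path) {
  jsonlite::write_json(unclass(profile), json_path, auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(profile_states(profile), tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(json_path, tsv_path))
}
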
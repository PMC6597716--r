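#' Ground-truth enzyme parameterisation for the synthetic-data generator
#'
#' An `enzyme_truth` object holds the activation and binding thermodynamics
#' plus unfolding parameters that fully determine an idealised enzyme's
#' temperature behaviour:
#' \deqn{k_{cat}(T) = (k_B T / h) \exp(-(\Delta H^\ddagger - T\Delta S^\ddagger)/(RT))}
#' \deqn{K_m(T) = c^\circ \exp((\Delta H_m - T\Delta S_m)/(RT))}
#' with binding thermodynamics in the association convention, so exothermic
#' binding (`dHm < 0`) gives a Km that worsens (increases) with temperature —
#' the behaviour seen in NAD-dependent dehydrogenases.
#'
#' @param name enzyme label.
#' @param dH_act activation enthalpy, kJ/mol.
#' @param dS_act activation entropy, kJ/(K mol).
#' @param dHm binding enthalpy (association convention), kJ/mol.
#' @param dSm binding entropy, kJ/(K mol).
#' @param Tm unfolding midpoint, degrees C.
#' @param dHvH van't Hoff unfolding enthalpy, kJ/mol.
#' @param baselines numeric length 4: native intercept (mdeg), native slope
#'   (mdeg per degree C), unfolded intercept, unfolded slope for the melt
#'   curve.
#' @return an object of class `enzyme_truth`.
#' @seealso [truth_kcat()], [truth_km()], [simulate_titration()],
#'   [simulate_melt()], [truth_preset()]
#' @export
enzyme_truth <- function(name, dH_act, dS_act, dHm, dSm,
                         Tm = 85, dHvH = 500,
                         baselines = c(-16, 0.02, -3, 0.01)) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(dH_act), is.numeric(dS_act),
            is.numeric(dHm), is.numeric(dSm),
            is.numeric(Tm), dHvH > 0, length(baselines) == 4)
  structure(
    list(name = name, dH_act = dH_act, dS_act = dS_act,
         dHm = dHm, dSm = dSm, Tm = Tm, dHvH = dHvH,
         baselines = as.numeric(baselines)),
    class = "enzyme_truth")
}

#' @export
print.enzyme_truth <- function(x, ...) {
  cat("Ground-truth enzyme:", x$name, "\n")
  cat(sprintf("  activation: dH = %.2f kJ/mol, dS = %.5f kJ/K/mol\n",
              x$dH_act, x$dS_act))
  cat(sprintf("  binding:    dHm = %.2f kJ/mol, dSm = %.5f kJ/K/mol\n",
              x$dHm, x$dSm))
  cat(sprintf("  unfolding:  Tm = %.1f C, dHvH = %.0f kJ/mol\n",
              x$Tm, x$dHvH))
  k25 <- truth_kcat(x, 298.15)
  km25 <- truth_km(x, 298.15)
  cat(sprintf("  at 25 C:    kcat = %.3g /s, Km = %.3g M\n", k25, km25))
  invisible(x)
}

#' Noise specification for synthetic datasets
#'
#' Velocities and ellipticities receive multiplicative Gaussian noise,
#' `y * (1 + e)`, `e ~ N(0, relative_sd)`. The same seed always reproduces
#' the identical dataset.
#'
#' @param relative_sd relative standard deviation (fraction, >= 0).
#' @param seed integer RNG seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0, seed = 1L) {
  stopifnot(is.numeric(relative_sd), relative_sd >= 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' True turnover number at a temperature
#'
#' Evaluates the Eyring law for a ground-truth enzyme; exact inverse of
#' [eyring_dg_act()].
#'
#' @param truth an [enzyme_truth()] object.
#' @param T_K temperature in Kelvin (> 0).
#' @param constants see [physical_constants()].
#' @return turnover number in 1/s.
#' @export
truth_kcat <- function(truth, T_K, constants = physical_constants()) {
  stopifnot(inherits(truth, "enzyme_truth"))
  if (any(T_K <= 0)) stop("temperature must be positive (Kelvin)")
  dG <- truth$dH_act - T_K * truth$dS_act
  (constants$k_B * T_K / constants$h) * exp(-dG / (constants$R * T_K))
}

#' True Michaelis constant at a temperature
#'
#' Evaluates `Km = c0 * exp(dG_m / (R T))` with `dG_m = dHm - T dSm` in the
#' association convention; round-trips through [binding_dg()].
#'
#' @inheritParams truth_kcat
#' @return Michaelis constant in mol/L.
#' @export
truth_km <- function(truth, T_K, constants = physical_constants()) {
  stopifnot(inherits(truth, "enzyme_truth"))
  if (any(T_K <= 0)) stop("temperature must be positive (Kelvin)")
  dGm <- truth$dHm - T_K * truth$dSm
  constants$c_standard * exp(dGm / (constants$R * T_K))
}

#' Derive a ground-truth enzyme from measured kinetic constants
#'
#' Builds an `enzyme_truth` whose Eyring/van't Hoff laws pass through a set
#' of measured (temperature, kcat, Km) triples: the activation enthalpy comes
#' from an Arrhenius regression of kcat, the binding enthalpy from a van't
#' Hoff regression of Km, and the entropies are set so that the law
#' reproduces the free energies at `T_anchor` exactly.
#'
#' @param df data frame with columns `temperature_C`, `kcat_per_s`,
#'   `Km_NAD_uM` (micromolar).
#' @param name enzyme label.
#' @param T_anchor_C anchoring temperature (degrees C) at which kcat and Km
#'   are reproduced exactly; defaults to the lowest supplied temperature.
#' @param Tm,dHvH,baselines unfolding parameters passed to [enzyme_truth()].
#' @inheritParams truth_kcat
#' @return an [enzyme_truth()] object.
#' @export
truth_from_constants <- function(df, name, T_anchor_C = min(df$temperature_C),
                                 Tm = 85, dHvH = 500,
                                 baselines = c(-16, 0.02, -3, 0.01),
                                 constants = physical_constants()) {
  stopifnot(all(c("temperature_C", "kcat_per_s", "Km_NAD_uM") %in% names(df)),
            nrow(df) >= 2)
  T_K <- celsius_to_kelvin(df$temperature_C)
  Ta <- celsius_to_kelvin(T_anchor_C)
  i <- which.min(abs(T_K - Ta))

  arr <- arrhenius_dh_act(data.frame(T_K = T_K, kcat = df$kcat_per_s),
                          T_ref = Ta, constants = constants)
  vh <- vanthoff_dhm(data.frame(T_K = T_K, Km = df$Km_NAD_uM * 1e-6),
                     convention = "association", constants = constants)
  dG_act <- eyring_dg_act(df$kcat_per_s[i], Ta, constants = constants)
  dG_m <- binding_dg(df$Km_NAD_uM[i] * 1e-6, Ta,
                     convention = "association", constants = constants)
  enzyme_truth(name = name,
               dH_act = arr$dH_act,
               dS_act = (arr$dH_act - dG_act) / Ta,
               dHm = vh$dH_m,
               dSm = (vh$dH_m - dG_m) / Ta,
               Tm = Tm, dHvH = dHvH, baselines = baselines)
}

#' Ground-truth presets
#'
#' Two calibrated presets: `"thermophile-like"` reproduces the kinetic
#' temperature dependence of the *T. thermophilus* IPMDH constants shipped
#' with the package, and `"mesophile-like"` that of the *E. coli* enzyme.
#' Unfolding parameters are set to values typical of the two classes (a
#' thermophilic homodimer melting near 88 degrees C, a mesophilic one near
#' 63 degrees C, van't Hoff enthalpies of several hundred kJ/mol).
#'
#' @param which `"thermophile-like"` or `"mesophile-like"`.
#' @return an [enzyme_truth()] object.
#' @export
#' @examples
#' truth_preset("thermophile-like")
truth_preset <- function(which = c("thermophile-like", "mesophile-like")) {
  which <- match.arg(which)
  tab <- ipmdh_constants()
  if (which == "thermophile-like") {
    df <- tab[tab$enzyme == "TtIPMDH" & tab$table == "T2", ]
    truth_from_constants(df, name = "thermophile-like",
                         Tm = 88, dHvH = 600,
                         baselines = c(-16, 0.02, -3, 0.01))
  } else {
    df <- tab[tab$enzyme == "EcIPMDH" & tab$table == "T2", ]
    truth_from_constants(df, name = "mesophile-like",
                         Tm = 63, dHvH = 450,
                         baselines = c(-15, 0.03, -2.5, 0.01))
  }
}
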
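#' Simulate an initial-velocity titration
#'
#' Generates noisy Michaelis-Menten velocities
#' `v = kcat [E] S / (Km + S) * (1 + e)`, `e ~ N(0, relative_sd)`, with kcat
#' and Km evaluated from the ground truth at the assay temperature. Mimics a
#' coenzyme titration at fixed substrate concentration.
#'
#' @param truth an [enzyme_truth()].
#' @param temperature_C assay temperature, degrees C.
#' @param conc_grid varied-ligand concentrations, mol/L, all positive.
#' @param enzyme_conc active-site concentration, mol/L.
#' @param noise a [noise_spec()].
#' @param varied_ligand label for the varied ligand.
#' @param fixed_conc fixed-ligand concentration, mol/L (metadata; the rate
#'   law is single-ligand saturation).
#' @param constants see [physical_constants()].
#' @return a [kinetic_series()] carrying `truth` for recovery tests.
#' @export
#' @examples
#' tr <- enzyme_truth("demo", dH_act = 80, dS_act = 0.02,
#'                    dHm = -60, dSm = -0.1)
#' s <- simulate_titration(tr, 25, conc_grid = truth_km(tr, 298.15) * 2^(-2:5),
#'                         enzyme_conc = 1e-8, noise = noise_spec(0.01, 42))
simulate_titration <- function(truth, temperature_C, conc_grid, enzyme_conc,
                               noise = noise_spec(0),
                               varied_ligand = "NAD", fixed_conc = 2e-4,
                               constants = physical_constants()) {
  stopifnot(inherits(truth, "enzyme_truth"), inherits(noise, "noise_spec"))
  if (length(conc_grid) == 0) stop("conc_grid must be non-empty")
  if (any(conc_grid <= 0)) stop("all concentrations must be positive")
  T_K <- celsius_to_kelvin(temperature_C)
  kcat <- truth_kcat(truth, T_K, constants)
  Km <- truth_km(truth, T_K, constants)
  v <- kcat * enzyme_conc * conc_grid / (Km + conc_grid)
  if (noise$relative_sd > 0) {
    eps <- with_seed(noise$seed,
                     stats::rnorm(length(v), 0, noise$relative_sd))
    v <- v * (1 + eps)
  }
  kinetic_series(enzyme = truth$name, temperature_C = temperature_C,
                 varied_ligand = varied_ligand, fixed_conc = fixed_conc,
                 conc = conc_grid, velocity = v, enzyme_conc = enzyme_conc,
                 truth = truth)
}

# Two-state fraction unfolded with zero heat-capacity change:
# dG_unf = dHvH (1 - T/Tm), f = 1 / (1 + exp(dG_unf / (R T))); T in Kelvin.
two_state_fraction <- function(T_C, Tm_C, dHvH,
                               constants = physical_constants()) {
  T_K <- celsius_to_kelvin(T_C)
  Tm_K <- celsius_to_kelvin(Tm_C)
  dG <- dHvH * (1 - T_K / Tm_K)
  1 / (1 + exp(dG / (constants$R * T_K)))
}

# Two-state melt signal with linear native/unfolded baselines (per deg C).
two_state_signal <- function(T_C, Tm_C, dHvH, aN, bN, aU, bU,
                             constants = physical_constants()) {
  f <- two_state_fraction(T_C, Tm_C, dHvH, constants)
  (1 - f) * (aN + bN * T_C) + f * (aU + bU * T_C)
}

#' Simulate a thermal melt curve
#'
#' Two-state unfolding with linear baselines:
#' `theta(T) = (1-f)(aN + bN T) + f (aU + bU T)` with
#' `f = 1/(1 + exp(dG_unf/(R T)))` and `dG_unf = dHvH (1 - T/Tm)` (T, Tm in
#' Kelvin). At `T = Tm` the unfolded fraction is exactly 1/2. Multiplicative
#' Gaussian noise is applied per point.
#'
#' @param truth an [enzyme_truth()] (uses `Tm`, `dHvH`, `baselines`).
#' @param T_grid temperatures, degrees C, increasing.
#' @param noise a [noise_spec()].
#' @param constants see [physical_constants()].
#' @return a [melt_curve()] carrying `truth`.
#' @export
simulate_melt <- function(truth, T_grid = seq(40, 100, by = 0.5),
                          noise = noise_spec(0),
                          constants = physical_constants()) {
  stopifnot(inherits(truth, "enzyme_truth"), inherits(noise, "noise_spec"))
  if (truth$Tm < min(T_grid) || truth$Tm > max(T_grid))
    warning("temperature grid does not span Tm; midpoint will be extrapolated")
  b <- truth$baselines
  theta <- two_state_signal(T_grid, truth$Tm, truth$dHvH,
                            b[1], b[2], b[3], b[4], constants)
  if (noise$relative_sd > 0) {
    eps <- with_seed(noise$seed,
                     stats::rnorm(length(theta), 0, noise$relative_sd))
    theta <- theta * (1 + eps)
  }
  melt_curve(T_grid, theta, enzyme = truth$name, truth = truth)
}
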
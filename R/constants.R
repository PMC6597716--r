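#' Physical constants used throughout the package
#'
#' Returns the constants used in the Eyring, Arrhenius and van't Hoff
#' calculations. Energies are handled in kJ/mol, so the gas constant is
#' returned in kJ/(K mol).
#'
#' @param R gas constant, kJ/(K mol).
#' @param h Planck constant, J s.
#' @param k_B Boltzmann constant, J/K.
#' @param c_standard standard-state concentration, mol/L. `Km` values are
#'   divided by this before any logarithm is taken.
#' @return A named list with components `R`, `h`, `k_B`, `c_standard`.
#'   Override only for reproducibility studies; all fitting functions take a
#'   `constants` argument defaulting to this.
#' @export
#' @examples
#' physical_constants()$R
physical_constants <- function(R = 8.314e-3,
                               h = 6.626e-34,
                               k_B = 1.381e-23,
                               c_standard = 1) {
  stopifnot(R > 0, h > 0, k_B > 0, c_standard > 0)
  list(R = R, h = h, k_B = k_B, c_standard = c_standard)
}

#' Convert Celsius to Kelvin
#' @param T_C temperature in degrees Celsius.
#' @return temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
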
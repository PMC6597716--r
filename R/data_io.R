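#' Published IPMDH kinetic constants shipped with the package
#'
#' Transcription of the steady-state kinetic constants of *T. thermophilus*
#' IPMDH, its engineered mutants and the *E. coli* enzyme, as printed:
#' Michaelis constants for NAD and D-3-IPM (micromolar, with standard
#' errors) and turnover numbers (1/s) at 25, 40 and 70 degrees C, together
#' with the printed fold-changes relative to TtIPMDH (`*_rel` columns;
#' `table` distinguishes the single-temperature mutant screen, `T1`, from
#' the multi-temperature characterisation, `T2`). A few printed relative
#' values are mutually inconsistent with the printed constants they
#' accompany (they were evidently computed from unrounded raw data);
#' [check_relative_consistency()] locates them.
#'
#' @return data frame with columns `enzyme`, `table`, `temperature_C`,
#'   `Km_IPM_uM`, `Km_IPM_se`, `Km_IPM_rel`, `Km_NAD_uM`, `Km_NAD_se`,
#'   `Km_NAD_rel`, `kcat_per_s`, `kcat_se`, `kcat_rel`.
#' @export
ipmdh_constants <- function() {
  path <- system.file("extdata", "ipmdh_kinetic_constants.csv",
                      package = "thermokin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Known beneficial substitutions of the characterised IPMDH mutants
#'
#' The substitutions carried by the constructs whose kinetics are tabulated
#' in [ipmdh_constants()]: mut#9 (Val272Ala + His273Gly), mut#17
#' (Ile130Cys), mut#21 (Ala220Thr).
#'
#' @return named list of [mutant_design()] objects.
#' @export
ipmdh_known_mutations <- function() {
  list(
    "mut#9" = mutant_design("mut#9",
      data.frame(pos = c(272, 273), from = c("V", "H"), to = c("A", "G"),
                 stringsAsFactors = FALSE), shell = 8),
    "mut#17" = mutant_design("mut#17",
      data.frame(pos = 130, from = "I", to = "C",
                 stringsAsFactors = FALSE), shell = 12),
    "mut#21" = mutant_design("mut#21",
      data.frame(pos = 220, from = "A", to = "T",
                 stringsAsFactors = FALSE), shell = 12))
}

#' Check printed relative values against recomputed ratios
#'
#' Recomputes each fold-change from the printed constants (2 significant
#' figures) and compares with the printed parenthesised value.
#'
#' @param constants data frame in the layout of [ipmdh_constants()].
#' @param quantity `"kcat"`, `"Km_NAD"` or `"Km_IPM"`.
#' @param table which printed table to check (`"T1"` or `"T2"`).
#' @param reference reference enzyme.
#' @return data frame with `enzyme`, `temperature_C`, `printed`,
#'   `computed`, `consistent`.
#' @export
check_relative_consistency <- function(constants = ipmdh_constants(),
                                       quantity = c("kcat", "Km_NAD",
                                                    "Km_IPM"),
                                       table = "T1",
                                       reference = "TtIPMDH") {
  quantity <- match.arg(quantity)
  vcol <- c(kcat = "kcat_per_s", Km_NAD = "Km_NAD_uM",
            Km_IPM = "Km_IPM_uM")[[quantity]]
  rcol <- c(kcat = "kcat_rel", Km_NAD = "Km_NAD_rel",
            Km_IPM = "Km_IPM_rel")[[quantity]]
  df <- constants[constants$table == table & !is.na(constants[[vcol]]), ]
  out <- do.call(rbind, lapply(split(df, df$temperature_C), function(d) {
    ref <- d[[vcol]][d$enzyme == reference]
    data.frame(enzyme = d$enzyme, temperature_C = d$temperature_C,
               printed = d[[rcol]],
               computed = signif(d[[vcol]] / ref, 2),
               stringsAsFactors = FALSE)
  }))
  out$consistent <- !is.na(out$printed) & out$printed == out$computed
  rownames(out) <- NULL
  out
}
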
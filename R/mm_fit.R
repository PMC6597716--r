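#' Fit the Michaelis-Menten equation to an initial-velocity titration
#'
#' Nonlinear least-squares fit of `v = Vmax S / (Km + S)` (unweighted by
#' default, matching standard steady-state practice), with
#' `kcat = Vmax / [E]`. Standard errors come from the covariance matrix of
#' the fit. Starting values are `Vmax0 = 1.2 max(v)` and `Km0` the
#' concentration closest to half-maximal velocity; both parameters are
#' bounded positive.
#'
#' @param series a [kinetic_series()] with at least 5 points at not-all-equal
#'   concentrations.
#' @param weights `"none"` (default) or `"1/v2"` for relative weighting.
#' @return object of class `mm_fit` with components `kcat`, `kcat_se`, `Km`,
#'   `Km_se`, `Vmax`, `converged`, `residuals`, `fit` (the underlying `nls`
#'   object) and `series`.
#' @seealso [coef.mm_fit()], [predict.mm_fit()], [summary.mm_fit()]
#' @export
#' @examples
#' tr <- enzyme_truth("demo", 80, 0.02, -60, -0.1)
#' s <- simulate_titration(tr, 25, truth_km(tr, 298.15) * 2^(-2:5), 1e-8)
#' fit_mm(s)
fit_mm <- function(series, weights = c("none", "1/v2")) {
  stopifnot(inherits(series, "kinetic_series"))
  weights <- match.arg(weights)
  S <- series$points$conc
  v <- series$points$velocity
  if (length(S) < 5)
    stop("Michaelis-Menten fitting requires at least 5 points, got ",
         length(S))
  if (length(unique(S)) < 2) stop("concentrations must not all be equal")

  vmax0 <- 1.2 * max(v)
  km0 <- S[which.min(abs(v - max(v) / 2))]
  w <- if (weights == "1/v2") 1 / pmax(v, .Machine$double.eps)^2 else
    rep(1, length(v))

  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      data = data.frame(S = S, v = v),
                      start = list(Vmax = vmax0, Km = km0),
                      weights = w,
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(kcat = NA_real_, kcat_se = NA_real_, Km = NA_real_,
                Km_se = NA_real_, Vmax = NA_real_, converged = FALSE,
                message = conditionMessage(fit), residuals = NULL,
                fit = NULL, series = series)
    class(out) <- "mm_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  at_bound <- cf[["Km"]] <= sqrt(.Machine$double.eps)
  out <- list(
    kcat = cf[["Vmax"]] / series$enzyme_conc,
    kcat_se = unname(se["Vmax"]) / series$enzyme_conc,
    Km = cf[["Km"]],
    Km_se = unname(se["Km"]),
    Vmax = cf[["Vmax"]],
    converged = fit$convInfo$isConv && !at_bound,
    message = if (at_bound) "Km estimate hit the lower bound" else
      fit$convInfo$stopMessage,
    residuals = stats::residuals(fit),
    fit = fit, series = series)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: %s at %g C (%s varied)\n",
              x$series$enzyme, x$series$temperature_C,
              x$series$varied_ligand))
  if (!x$converged) cat("  NOT converged:", x$message, "\n")
  cat(sprintf("  kcat = %.4g +/- %.2g /s\n", x$kcat, x$kcat_se))
  cat(sprintf("  Km   = %.4g +/- %.2g M\n", x$Km, x$Km_se))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, Km = object$Km)
}

#' @export
summary.mm_fit <- function(object, ...) {
  res <- object$residuals
  structure(list(fit = object,
                 rss = if (is.null(res)) NA_real_ else sum(res^2),
                 sigma = if (is.null(res)) NA_real_ else
                   sqrt(sum(res^2) / max(1, length(res) - 2)),
                 n = nrow(object$series$points)),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d, RSS = %.3g, sigma = %.3g\n", x$n, x$rss, x$sigma))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$series$points$conc else newdata$conc
  object$Vmax * S / (object$Km + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$series$points$velocity - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  S <- x$series$points$conc
  graphics::plot(S, x$series$points$velocity, log = "x",
                 xlab = "[ligand] (M)", ylab = "v (M/s)",
                 main = sprintf("%s, %g C", x$series$enzyme,
                                x$series$temperature_C), ...)
  grid_S <- exp(seq(log(min(S)), log(max(S)), length.out = 100))
  graphics::lines(grid_S, predict(x, data.frame(conc = grid_S)))
  invisible(x)
}

#' Specific activity from an absorbance slope
#'
#' Converts a rate of absorbance increase (NADH formation followed at
#' 340 nm) into enzyme units per mg protein, with one unit defined as 1
#' micromole NADH formed per minute.
#'
#' @param slope absorbance change per minute.
#' @param extinction molar extinction coefficient, 1/(M cm); NADH at 340 nm
#'   is 6220 by default.
#' @param path cuvette path length, cm.
#' @param volume assay volume, L.
#' @param mass protein mass in the assay, mg.
#' @return specific activity in U/mg.
#' @export
#' @examples
#' specific_activity(0.0622, volume = 1e-3, mass = 0.01)  # 1 U/mg
specific_activity <- function(slope, volume, mass,
                              extinction = 6220, path = 1) {
  if (any(c(slope, volume, mass, extinction, path) <= 0))
    stop("all inputs to specific_activity must be positive")
  (slope / (extinction * path)) * volume * 1e6 / mass
}

#' Fold-changes relative to a reference enzyme
#'
#' Builds the "value (relative)" presentation used in kinetic-constant
#' tables: each enzyme's value divided by the reference enzyme's value,
#' rounded to 2 significant figures.
#'
#' @param values named numeric vector (names are enzyme labels), all
#'   positive.
#' @param reference name of the reference enzyme (must be present).
#' @param digits significant figures for the relative value.
#' @return data frame of class `relative_table` with columns `enzyme`,
#'   `value`, `relative`.
#' @export
#' @examples
#' relative_table(c(TtIPMDH = 0.37, "mut#9" = 3.5), "TtIPMDH")
relative_table <- function(values, reference, digits = 2) {
  if (!reference %in% names(values))
    stop("reference enzyme '", reference, "' not among the values")
  if (any(values <= 0)) stop("all values must be positive")
  out <- data.frame(enzyme = names(values),
                    value = unname(values),
                    relative = signif(unname(values) / values[[reference]],
                                      digits),
                    stringsAsFactors = FALSE)
  class(out) <- c("relative_table", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' @export
print.relative_table <- function(x, ...) {
  cat("Values relative to", attr(x, "reference"), "in parentheses:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %g (%g)\n", x$enzyme[i], x$value[i],
                x$relative[i]))
  invisible(x)
}

#' kcat fold-changes across temperatures
#'
#' For each enzyme, reports the kcat fold-change over the reference at each
#' temperature and whether the benefit decreases with temperature
#' (`fold(25) >= fold(40) >= fold(70)` style monotonicity) — the signature
#' of mutations that help catalytic turnover most at low temperature.
#'
#' @param constants data frame with columns `enzyme`, `temperature_C`,
#'   `kcat_per_s`.
#' @param reference reference enzyme present at every temperature.
#' @return list of class `fold_change_report`: `folds` (data frame enzyme x
#'   temperature of fold-changes) and `decreasing` (named logical per
#'   enzyme).
#' @export
fold_change_report <- function(constants, reference = "TtIPMDH") {
  need <- c("enzyme", "temperature_C", "kcat_per_s")
  stopifnot(all(need %in% names(constants)))
  temps <- sort(unique(constants$temperature_C))
  enz <- unique(constants$enzyme)
  ref_k <- vapply(temps, function(tc) {
    k <- constants$kcat_per_s[constants$enzyme == reference &
                                constants$temperature_C == tc]
    if (length(k) != 1)
      stop("reference '", reference, "' must appear exactly once at ",
           tc, " C")
    k
  }, numeric(1))
  folds <- t(vapply(enz, function(e) {
    vapply(seq_along(temps), function(i) {
      k <- constants$kcat_per_s[constants$enzyme == e &
                                  constants$temperature_C == temps[i]]
      if (length(k) != 1) NA_real_ else k / ref_k[i]
    }, numeric(1))
  }, numeric(length(temps))))
  colnames(folds) <- paste0(temps, "C")
  rownames(folds) <- enz
  decreasing <- apply(folds, 1, function(f) {
    f <- f[!is.na(f)]
    length(f) < 2 || all(diff(f) <= 1e-12)
  })
  structure(list(folds = as.data.frame(folds), decreasing = decreasing,
                 reference = reference),
            class = "fold_change_report")
}

#' @export
print.fold_change_report <- function(x, ...) {
  cat("kcat fold-change relative to", x$reference, "by temperature:\n")
  df <- x$folds
  df$decreasing_with_T <- x$decreasing
  print(round(df, 2))
  invisible(x)
}
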
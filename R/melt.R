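#' Fit a two-state thermal unfolding curve
#'
#' Least-squares fit of the two-state van't Hoff model with linear native
#' and unfolded baselines to an ellipticity-versus-temperature curve:
#' `theta(T) = (1-f)(aN + bN T) + f (aU + bU T)` with
#' `f = 1/(1 + exp(dHvH (1 - T/Tm) / (R T)))` (T, Tm in Kelvin internally;
#' the interface uses degrees C). A model-free fallback
#' (`method = "derivative"`) takes the extremum of a locally smoothed
#' derivative and is useful for irreversible or asymmetric melts, which are
#' common for thermophilic proteins.
#'
#' @param curve a [melt_curve()].
#' @param method `"two-state"` (default) or `"derivative"`.
#' @param transition_snr minimum ratio of signal range to local noise below
#'   which the curve is declared to have no visible transition.
#' @param constants see [physical_constants()].
#' @return object of class `melt_fit` with `Tm` (degrees C), `Tm_se`,
#'   `dHvH` (kJ/mol), `dHvH_se`, `baselines` (aN, bN, aU, bU), `converged`,
#'   `method`, `fit`, `curve`. A flat curve returns
#'   `converged = FALSE` with `message = "no transition detected"`.
#' @seealso [delta_tm()], [fraction_unfolded()]
#' @export
#' @examples
#' tr <- truth_preset("thermophile-like")
#' fit_melt(simulate_melt(tr, noise = noise_spec(0.01, 1)))
fit_melt <- function(curve, method = c("two-state", "derivative"),
                     transition_snr = 5,
                     constants = physical_constants()) {
  stopifnot(inherits(curve, "melt_curve"))
  method <- match.arg(method)
  Tc <- curve$points$temperature_C
  y <- curve$points$ellipticity

  # local noise: scaled second differences are model-free noise estimates
  noise <- stats::median(abs(diff(y, differences = 2))) / sqrt(6)
  if (diff(range(y)) <= transition_snr * max(noise, .Machine$double.eps)) {
    out <- list(Tm = NA_real_, Tm_se = NA_real_, dHvH = NA_real_,
                dHvH_se = NA_real_, baselines = rep(NA_real_, 4),
                converged = FALSE, message = "no transition detected",
                method = method, fit = NULL, curve = curve)
    class(out) <- "melt_fit"
    return(out)
  }

  start <- melt_start_values(Tc, y)
  if (method == "derivative") {
    out <- list(Tm = start$Tm, Tm_se = NA_real_, dHvH = NA_real_,
                dHvH_se = NA_real_,
                baselines = c(start$aN, start$bN, start$aU, start$bU),
                converged = TRUE, message = "model-free derivative midpoint",
                method = method, fit = NULL, curve = curve)
    class(out) <- "melt_fit"
    return(out)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(Tc, Tm, dHvH, aN, bN, aU, bU, constants),
      data = data.frame(Tc = Tc, y = y),
      start = list(Tm = start$Tm, dHvH = start$dHvH,
                   aN = start$aN, bN = start$bN,
                   aU = start$aU, bU = start$bU),
      lower = c(Tm = min(Tc) - 20, dHvH = 10,
                aN = -Inf, bN = -Inf, aU = -Inf, bU = -Inf),
      upper = c(Tm = max(Tc) + 20, dHvH = 5000,
                aN = Inf, bN = Inf, aU = Inf, bU = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(Tm = NA_real_, Tm_se = NA_real_, dHvH = NA_real_,
                dHvH_se = NA_real_, baselines = rep(NA_real_, 4),
                converged = FALSE, message = conditionMessage(fit),
                method = method, fit = NULL, curve = curve)
    class(out) <- "melt_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 6),
                                                     names(cf)))
  in_range <- cf[["Tm"]] >= min(Tc) && cf[["Tm"]] <= max(Tc)
  out <- list(Tm = cf[["Tm"]], Tm_se = unname(se["Tm"]),
              dHvH = cf[["dHvH"]], dHvH_se = unname(se["dHvH"]),
              baselines = unname(cf[c("aN", "bN", "aU", "bU")]),
              converged = fit$convInfo$isConv && in_range,
              message = if (!in_range)
                "fitted Tm outside the data range" else
                fit$convInfo$stopMessage,
              method = method, fit = fit, curve = curve)
  class(out) <- "melt_fit"
  out
}

# Starting values: baselines from the outer 15% of points, Tm from the
# extremum of a smoothed derivative, dHvH from a generic 300 kJ/mol.
melt_start_values <- function(Tc, y) {
  n <- length(Tc)
  k <- max(3, floor(0.15 * n))
  lo <- stats::lm(y ~ Tc, data = data.frame(Tc = Tc[1:k], y = y[1:k]))
  hi <- stats::lm(y ~ Tc, data = data.frame(Tc = Tc[(n - k + 1):n],
                                            y = y[(n - k + 1):n]))
  ys <- smooth_running_mean(y, max(3, floor(n / 20)))
  dy <- diff(ys) / diff(Tc)
  Tmid <- (Tc[-1] + Tc[-n]) / 2
  # restrict to the interior so baseline jitter cannot win
  inner <- Tmid > stats::quantile(Tc, 0.05) & Tmid < stats::quantile(Tc, 0.95)
  i <- which(inner)[which.max(abs(dy[inner]))]
  list(Tm = Tmid[i], dHvH = 300,
       aN = unname(stats::coef(lo)[1]), bN = unname(stats::coef(lo)[2]),
       aU = unname(stats::coef(hi)[1]), bU = unname(stats::coef(hi)[2]))
}

smooth_running_mean <- function(y, k) {
  if (k < 2) return(y)
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Melt fit (%s): %s\n", x$method, x$curve$enzyme))
  if (!x$converged) {
    cat("  NOT converged:", x$message, "\n")
  } else {
    cat(sprintf("  Tm = %.2f +/- %.2g C", x$Tm, x$Tm_se))
    if (!is.na(x$dHvH))
      cat(sprintf(", dHvH = %.0f +/- %.2g kJ/mol", x$dHvH, x$dHvH_se))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(Tm = object$Tm, dHvH = object$dHvH,
    aN = object$baselines[1], bN = object$baselines[2],
    aU = object$baselines[3], bU = object$baselines[4])
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  Tc <- if (is.null(newdata)) object$curve$points$temperature_C else
    newdata$temperature_C
  b <- object$baselines
  two_state_signal(Tc, object$Tm, object$dHvH, b[1], b[2], b[3], b[4])
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$curve$points$ellipticity - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$points$temperature_C, x$curve$points$ellipticity,
                 xlab = "temperature (C)", ylab = "ellipticity (mdeg)",
                 main = x$curve$enzyme, ...)
  if (x$converged && !is.na(x$dHvH)) {
    Tg <- seq(min(x$curve$points$temperature_C),
              max(x$curve$points$temperature_C), length.out = 200)
    graphics::lines(Tg, predict(x, data.frame(temperature_C = Tg)))
    graphics::abline(v = x$Tm, lty = 2)
  }
  invisible(x)
}

#' Fraction unfolded implied by a melt fit
#' @param fit a converged two-state [fit_melt()] result.
#' @param temperature_C temperatures at which to evaluate (defaults to the
#'   curve's).
#' @return data frame `temperature_C`, `fraction_unfolded`.
#' @export
fraction_unfolded <- function(fit, temperature_C = NULL) {
  stopifnot(inherits(fit, "melt_fit"))
  if (!fit$converged || is.na(fit$dHvH))
    stop("fraction_unfolded needs a converged two-state fit")
  Tc <- if (is.null(temperature_C)) fit$curve$points$temperature_C else
    temperature_C
  data.frame(temperature_C = Tc,
             fraction_unfolded = two_state_fraction(Tc, fit$Tm, fit$dHvH))
}

#' Melting-point difference between two fits
#'
#' `Tm(mutant) - Tm(reference)` with the standard error propagated in
#' quadrature.
#'
#' @param mutant,reference converged [fit_melt()] results.
#' @return list of class `delta_tm`: `dTm` (degrees C), `se`.
#' @export
delta_tm <- function(mutant, reference) {
  stopifnot(inherits(mutant, "melt_fit"), inherits(reference, "melt_fit"))
  if (!mutant$converged || !reference$converged)
    stop("delta_tm requires converged fits on both sides")
  se <- sqrt(sum(c(mutant$Tm_se, reference$Tm_se)^2, na.rm = TRUE))
  structure(list(dTm = mutant$Tm - reference$Tm, se = se,
                 mutant = mutant$curve$enzyme,
                 reference = reference$curve$enzyme),
            class = "delta_tm")
}

#' @export
print.delta_tm <- function(x, ...) {
  cat(sprintf("delta Tm (%s - %s) = %.2f +/- %.2g C\n",
              x$mutant, x$reference, x$dTm, x$se))
  invisible(x)
}
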
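#' Fit the stability-activity trade-off line
#'
#' Ordinary least squares of `log10(specific activity at 25 C)` on the
#' unfolding midpoint temperature. By convention the trade-off line is
#' defined by the wild-type enzymes only; engineered mutants are then scored
#' by their deviation from that line ([deviation_from_line()]), so a mutant
#' escaping the trade-off sits above it.
#'
#' @param points data frame with columns `enzyme`, `activity` (U/mg, > 0),
#'   `Tm_C`, and optionally `group` (`"wild-type"` or `"mutant"`; all rows
#'   are treated as wild-type if absent).
#' @param fit_group which group defines the line (default `"wild-type"`).
#' @return object of class `tradeoff_fit` with `slope` (log10 units per
#'   degree C), `intercept`, `r` (Pearson correlation, signed like the
#'   slope), `residuals` (named, fitting points only), `lm` and `points`.
#' @export
#' @examples
#' pts <- data.frame(enzyme = c("A", "B", "C"),
#'                   activity = c(100, 10, 1), Tm_C = c(50, 70, 90))
#' fit_tradeoff(pts)
fit_tradeoff <- function(points, fit_group = "wild-type") {
  stopifnot(all(c("enzyme", "activity", "Tm_C") %in% names(points)))
  if (any(points$activity <= 0))
    stop("activities must be positive (their logarithm defines the fit)")
  if (!"group" %in% names(points)) points$group <- fit_group
  base <- points[points$group == fit_group, ]
  if (nrow(base) < 3)
    stop("at least 3 points in group '", fit_group,
         "' are needed to define the trade-off line")
  df <- data.frame(y = log10(base$activity), Tm = base$Tm_C)
  fit <- stats::lm(y ~ Tm, data = df)
  slope <- unname(stats::coef(fit)[2])
  r <- stats::cor(df$Tm, df$y)
  res <- stats::setNames(stats::residuals(fit), base$enzyme)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, residuals = res, lm = fit, points = points,
                 fit_group = fit_group),
            class = "tradeoff_fit")
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat(sprintf(
    "Stability-activity trade-off: log10(activity) = %.4f %+.4f * Tm\n",
    x$intercept, x$slope))
  cat(sprintf("  Pearson r = %.3f over %d %s point(s)\n", x$r,
              length(x$residuals), x$fit_group))
  invisible(x)
}

#' @export
coef.tradeoff_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.tradeoff_fit <- function(object, newdata = NULL, ...) {
  Tm <- if (is.null(newdata)) object$points$Tm_C else newdata$Tm_C
  object$intercept + object$slope * Tm
}

#' @export
residuals.tradeoff_fit <- function(object, ...) object$residuals

#' @export
plot.tradeoff_fit <- function(x, ...) {
  graphics::plot(x$points$Tm_C, log10(x$points$activity),
                 xlab = "Tm (C)", ylab = "log10 specific activity (U/mg)",
                 pch = ifelse(x$points$group == x$fit_group, 19, 1), ...)
  graphics::abline(x$intercept, x$slope, lty = 3)
  invisible(x)
}

#' Deviation of a point from the trade-off line
#'
#' Observed `log10(activity)` minus the line's prediction at the point's
#' Tm; positive values lie above the line (more active than the trade-off
#' allows), the signature of a stability-activity "escaper".
#'
#' @param fit a [fit_tradeoff()] result.
#' @param points data frame with columns `activity` and `Tm_C` (and
#'   optionally `enzyme` for naming).
#' @return named numeric vector of deviations in log10 activity units.
#' @export
deviation_from_line <- function(fit, points) {
  stopifnot(inherits(fit, "tradeoff_fit"),
            all(c("activity", "Tm_C") %in% names(points)))
  if (any(points$activity <= 0)) stop("activities must be positive")
  dev <- log10(points$activity) - predict(fit, points)
  if ("enzyme" %in% names(points)) names(dev) <- points$enzyme
  dev
}
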
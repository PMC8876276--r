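#' Calibration series of signal versus label concentration
#'
#' Measurements of the per-molecule scaled signal on standards of known
#' label concentration (the standards span 2.6--260 uM, bracketing the
#' ~100 uM endo-lysosomal accumulation expected from receptor numbers and
#' endosomal volume).
#'
#' @param concentration_uM strictly positive concentrations.
#' @param signal measured scaled signal (ASO or ligand) at each concentration.
#' @param signal_sd optional non-negative standard deviation of each signal.
#' @param label_kind `"ASO"` or `"LIGAND"`.
#' @return `data.frame` of class `calibration_series`.
#' @export
calibration_series <- function(concentration_uM, signal, signal_sd = 0,
                               label_kind = c("ASO", "LIGAND")) {
  label_kind <- match.arg(label_kind)
  if (any(concentration_uM <= 0)) stop("concentrations must be strictly positive")
  if (any(signal_sd < 0)) stop("signal_sd must be non-negative")
  if (length(signal) != length(concentration_uM))
    stop("signal and concentration_uM must have equal length")
  out <- data.frame(concentration_uM = as.numeric(concentration_uM),
                    signal = as.numeric(signal),
                    signal_sd = rep_len(as.numeric(signal_sd),
                                        length(concentration_uM)))
  attr(out, "label_kind") <- label_kind
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Fit the linear response of signal versus concentration
#'
#' Ordinary least-squares fit `signal ~ concentration`; the scaled signals
#' respond linearly across the working range, so the slope is the
#' per-micromolar response used for limit-of-detection estimation.
#'
#' @param series a [calibration_series()] with at least 3 distinct
#'   concentrations.
#' @return object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `lod_uM` (`NA` until [estimate_lod()] is applied) and the
#'   underlying `lm` fit.
#' @export
fit_linear_response <- function(series) {
  stopifnot(inherits(series, "calibration_series"))
  if (length(unique(series$concentration_uM)) < 3L)
    stop("at least 3 distinct concentrations are required")
  fit <- stats::lm(signal ~ concentration_uM, data = series)
  ss_tot <- sum((series$signal - mean(series$signal))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, lod_uM = NA_real_,
                 fit = fit, series = series),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration_fit: signal = %.4g + %.4g x conc_uM (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  if (!is.na(x$lod_uM)) cat(sprintf("  LOD: %.3g uM\n", x$lod_uM))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, concentration_uM, ...) {
  object$intercept + object$slope * concentration_uM
}

#' Limit of detection from a calibration fit and background statistics
#'
#' The standard analytical-chemistry rule: the LOD is the concentration
#' whose predicted signal equals the background mean plus `k_sigma` times
#' the background standard deviation,
#' `(background_mean + k_sigma * background_sd - intercept) / slope`,
#' floored at 0. The background is the natural-abundance (unlabelled)
#' signal distribution.
#'
#' @param fit a [fit_linear_response()] result with positive slope.
#' @param background_mean,background_sd background signal statistics.
#' @param k_sigma detection multiplier (default 3).
#' @return LOD in uM (also stored when the fit is updated by the caller).
#' @export
estimate_lod <- function(fit, background_mean = 0, background_sd, k_sigma = 3) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (background_sd < 0) stop("background_sd must be non-negative")
  if (fit$slope <= 0) stop("uncalibratable: non-positive slope")
  max(0, (background_mean + k_sigma * background_sd - fit$intercept) / fit$slope)
}

#' Linearity between the two labels of an equimolar dual-label standard
#'
#' Regresses the 127I ligand signal on the 34S ASO signal across matched
#' concentrations; a linear relationship validates that the two labels can
#' be quantified against each other.
#'
#' @param series_i ligand-signal [calibration_series()].
#' @param series_s ASO-signal [calibration_series()] at the same
#'   concentrations.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
check_dual_label_linearity <- function(series_i, series_s) {
  stopifnot(inherits(series_i, "calibration_series"),
            inherits(series_s, "calibration_series"))
  oi <- order(series_i$concentration_uM)
  os <- order(series_s$concentration_uM)
  ci <- series_i$concentration_uM[oi]
  cs <- series_s$concentration_uM[os]
  if (length(ci) != length(cs) || !isTRUE(all.equal(ci, cs)))
    stop("concentration sets not matched")
  x <- series_s$signal[os]
  y <- series_i$signal[oi]
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot == 0) 0 else
         1 - sum(stats::residuals(fit)^2) / ss_tot)
}
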
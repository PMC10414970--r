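## Monotone ratio <-> pH mapping fitted to standards. The default is a
## monotone piecewise-cubic (Hyman) interpolant through the standards;
## a 4-parameter logistic is available because fluorescein-family dyes
## follow a single-pKa titration. Queries outside the fitted range are
## clamped and flagged, never extrapolated: the dye saturates outside
## its response range.

logistic4 <- function(pH, rMin, rMax, pKa, slope) {
  rMin + (rMax - rMin) / (1 + 10^(slope * (pKa - pH)))
}

## Forward evaluation ratio = f(pH) for a fitted curve (no clamping).
curveForward <- function(curve, pH) {
  if (curve@model == "interpolating") {
    f <- stats::splinefun(curve@standards$pH, curve@standards$ratio,
                          method = "hyman")
    f(pH)
  } else {
    do.call(logistic4, c(list(pH = pH), curve@params))
  }
}

#' Fit a calibration curve to (pH, ratio) standards
#'
#' The interpolating model is a monotone Hyman spline through the
#' standards and requires strictly increasing ratios; the sigmoid model
#' is a 4-parameter logistic \code{rMin + (rMax - rMin) / (1 +
#' 10^(slope (pKa - pH)))} fitted by Levenberg-Marquardt least squares
#' with a positivity constraint on the slope.
#'
#' @param standards data.frame (pH, ratio); duplicates averaged.
#' @param model "interpolating" (default) or "sigmoid".
#' @return a \code{CalibrationCurve}; its \code{rms} slot reports the
#'   residual RMS (0 for the interpolating model).
#' @export
fitCalibration <- function(standards, model = c("interpolating", "sigmoid")) {
  model <- match.arg(model)
  agg <- stats::aggregate(list(ratio = standards$ratio),
                          by = list(pH = standards$pH), FUN = mean)
  agg <- agg[order(agg$pH), , drop = FALSE]
  rownames(agg) <- NULL
  if (nrow(agg) < 3)
    rzStop("need at least 3 distinct pH standards", "insufficient_standards")
  if (model == "interpolating") {
    if (any(diff(agg$ratio) <= 0))
      rzStop(paste0("standards are not strictly increasing in ratio with pH; ",
                    "the interpolating model requires monotone standards ",
                    "(consider model = 'sigmoid')"), "monotonicity")
    curve <- new("CalibrationCurve", standards = agg, model = model,
                 params = list(), pHRange = range(agg$pH),
                 ratioRange = range(agg$ratio), rms = 0)
  } else {
    rngR <- diff(range(agg$ratio))
    start <- list(rMin = min(agg$ratio) - 0.05 * rngR,
                  rMax = max(agg$ratio) + 0.5 * rngR,
                  pKa = stats::median(agg$pH), slope = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ratio ~ rMin + (rMax - rMin) / (1 + 10^(slope * (pKa - pH))),
        data = agg, start = start,
        lower = c(rMin = 0, rMax = 0, pKa = min(agg$pH) - 5, slope = 0.05),
        upper = c(rMin = Inf, rMax = Inf, pKa = max(agg$pH) + 5, slope = 10),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) rzStop(
        paste0("sigmoid fit did not converge: ", conditionMessage(e)), "fit"))
    cf <- as.list(stats::coef(fit))
    if (cf$rMax <= cf$rMin)
      rzStop("sigmoid fit is not increasing (rMax <= rMin)", "fit")
    rms <- sqrt(mean(stats::resid(fit)^2))
    curve <- new("CalibrationCurve", standards = agg, model = model,
                 params = cf, pHRange = range(agg$pH),
                 ratioRange = as.numeric(logistic4(range(agg$pH), cf$rMin,
                                                   cf$rMax, cf$pKa, cf$slope)),
                 rms = rms)
  }
  ## monotonicity check on a dense grid
  grid <- seq(curve@pHRange[1], curve@pHRange[2], length.out = 512)
  if (any(diff(curveForward(curve, grid)) <= 0))
    rzStop("fitted mapping is not strictly increasing on the standards' range",
           "monotonicity")
  curve
}

#' Convert pH to F488/405 ratio
#'
#' @param curve a fitted \code{CalibrationCurve}.
#' @param pH numeric vector.
#' @return numeric ratio vector with attribute \code{"clamped"}, a
#'   logical vector marking queries outside the fitted pH range (these
#'   return the boundary ratio).
#' @export
pHToRatio <- function(curve, pH) {
  lo <- curve@pHRange[1]; hi <- curve@pHRange[2]
  clamped <- pH < lo | pH > hi
  pHc <- pmin(pmax(pH, lo), hi)
  out <- curveForward(curve, pHc)
  attr(out, "clamped") <- clamped
  out
}

#' Convert F488/405 ratio to pH
#'
#' The monotone forward map is inverted numerically (bisection to 1e-10
#' in pH), so \code{pHToRatio(curve, ratioToPH(curve, r))} returns
#' \code{r} to better than 1e-6 inside the fitted range. Out-of-range
#' ratios are clamped to the boundary pH and flagged.
#'
#' @param curve a fitted \code{CalibrationCurve}.
#' @param ratio numeric vector.
#' @return numeric pH vector with attribute \code{"clamped"}.
#' @export
ratioToPH <- function(curve, ratio) {
  lo <- curve@ratioRange[1]; hi <- curve@ratioRange[2]
  clamped <- ratio < lo | ratio > hi
  rc <- pmin(pmax(ratio, lo), hi)
  pLo <- rep(curve@pHRange[1], length(rc))
  pHi <- rep(curve@pHRange[2], length(rc))
  for (i in seq_len(60)) {
    mid <- (pLo + pHi) / 2
    fm <- curveForward(curve, mid)
    below <- fm < rc
    pLo[below] <- mid[below]
    pHi[!below] <- mid[!below]
  }
  out <- (pLo + pHi) / 2
  ## snap exact standard nodes (interpolating model hits them exactly)
  attr(out, "clamped") <- clamped
  out
}

#' Apply a calibration curve to a profile's bin ratios
#'
#' Bin ratios are converted to pH; calibrated pH is never re-averaged
#' across bins (calibration and aggregation do not commute).
#'
#' @param profile a \code{PHProfile}.
#' @param curve a \code{CalibrationCurve}.
#' @return the profile with its pH column filled and
#'   \code{calibrated = TRUE}.
#' @export
calibrateProfile <- function(profile, curve) {
  b <- profile@bins
  ok <- !is.na(b$meanRatio)
  pH <- rep(NA_real_, nrow(b))
  if (any(ok)) {
    v <- ratioToPH(curve, b$meanRatio[ok])
    pH[ok] <- as.numeric(v)
    nCl <- sum(attr(v, "clamped"))
    if (nCl > 0)
      rzLog(sprintf("%d bin ratios outside the calibration range (clamped)",
                    nCl))
  }
  b$pH <- pH
  initialize(profile, bins = b, calibrated = TRUE)
}

#' Serialize a calibration curve to JSON
#' @param curve a \code{CalibrationCurve}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
saveCalibration <- function(curve, path) {
  writeResultJSON(list(
    format = "rhizopH-calibration", model = curve@model,
    standards = curve@standards, params = curve@params,
    pH_range = curve@pHRange, ratio_range = curve@ratioRange,
    rms = curve@rms), path)
}

#' Read a calibration curve from JSON written by [saveCalibration()]
#' @param path JSON path.
#' @return a \code{CalibrationCurve} (interpolating curves are refitted
#'   from the stored standards; sigmoid parameters are restored as-is).
#' @export
loadCalibration <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- as.data.frame(j$standards)
  if (identical(j$model, "interpolating")) {
    fitCalibration(std, "interpolating")
  } else {
    new("CalibrationCurve", standards = std, model = "sigmoid",
        params = as.list(j$params), pHRange = as.numeric(j$pH_range),
        ratioRange = as.numeric(j$ratio_range), rms = as.numeric(j$rms))
  }
}
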
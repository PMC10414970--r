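#' @import methods
NULL

## ---------------------------------------------------------------------------
## RunConfig
## ---------------------------------------------------------------------------

#' Run configuration for the pH-profiling pipeline
#'
#' Holds the geometric and photometric parameters of a run. The surface
#' band defaults (10-25 px off the root, 20 px longitudinal bins, hence
#' 15 x 20 px bins) follow the published analysis convention for this
#' imaging setup.
#'
#' @slot bandMinPx inner band edge, px off the root surface (default 10).
#' @slot bandMaxPx outer band edge, px (default 25).
#' @slot binLengthPx longitudinal bin length along the midline, px (default 20).
#' @slot background488,background405 per-channel constant offsets subtracted
#'   before ratioing (default 0).
#' @slot thresholdMethod segmentation threshold method; only \code{"otsu"}.
#' @slot minAreaPx minimum object area kept during segmentation.
#' @slot closeRadiusPx radius of the morphological closing brush.
#' @slot nMinPixels minimum pixels for a bin to be marked valid (default 30).
#' @slot maxDistUm profiles are truncated at this distance from the tip.
#' @slot ratioFloor bins whose summed 405 signal falls below
#'   \code{ratioFloor * max(sum405)} are marked invalid.
#' @slot seed integer seed for stochastic steps (bootstrap); NA = unset.
#' @exportClass RunConfig
setClass("RunConfig", representation(
  bandMinPx = "numeric", bandMaxPx = "numeric", binLengthPx = "numeric",
  background488 = "numeric", background405 = "numeric",
  thresholdMethod = "character", minAreaPx = "numeric",
  closeRadiusPx = "numeric", nMinPixels = "numeric",
  maxDistUm = "numeric", ratioFloor = "numeric", seed = "numeric"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!(object@bandMinPx > 0)) msg <- c(msg, "bandMinPx must be > 0")
  if (!(object@bandMinPx < object@bandMaxPx))
    msg <- c(msg, "bandMinPx must be < bandMaxPx")
  if (object@binLengthPx < 1) msg <- c(msg, "binLengthPx must be >= 1")
  if (object@background488 < 0 || object@background405 < 0)
    msg <- c(msg, "backgrounds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#'
#' @param bandMinPx,bandMaxPx surface band bounds in px (defaults 10, 25).
#' @param binLengthPx longitudinal bin length in px (default 20).
#' @param background488,background405 constant channel offsets (default 0).
#' @param thresholdMethod currently \code{"otsu"}.
#' @param minAreaPx minimum segmented-object area (default 200 px).
#' @param closeRadiusPx morphological closing radius (default 3 px).
#' @param nMinPixels minimum pixels per valid bin (default 30).
#' @param maxDistUm profile truncation distance from tip (default 1000).
#' @param ratioFloor relative floor on a bin's summed 405 signal (default 1e-6).
#' @param seed optional integer seed.
#' @return a \code{RunConfig} object.
#' @examples
#' cfg <- runConfig()
#' cfg
#' @export
runConfig <- function(bandMinPx = 10, bandMaxPx = 25, binLengthPx = 20,
                      background488 = 0, background405 = 0,
                      thresholdMethod = "otsu", minAreaPx = 200,
                      closeRadiusPx = 3, nMinPixels = 30,
                      maxDistUm = 1000, ratioFloor = 1e-6, seed = NA_real_) {
  new("RunConfig", bandMinPx = bandMinPx, bandMaxPx = bandMaxPx,
      binLengthPx = binLengthPx, background488 = background488,
      background405 = background405, thresholdMethod = thresholdMethod,
      minAreaPx = minAreaPx, closeRadiusPx = closeRadiusPx,
      nMinPixels = nMinPixels, maxDistUm = maxDistUm,
      ratioFloor = ratioFloor, seed = seed)
}

## ---------------------------------------------------------------------------
## ChannelStack
## ---------------------------------------------------------------------------

#' Two-excitation-channel image time series
#'
#' The raw input container: per frame one image acquired under 488 nm
#' excitation and one under 405 nm excitation (shared emission band),
#' stored as an ny x nx x 2 x T array (channels ordered 488, 405).
#' Image coordinates: x = column, y = row, y increases downward; the
#' default gravity vector (0, 1) points down the image.
#'
#' @slot data numeric array, dim (ny, nx, 2, T), nonnegative.
#' @slot pixelSize microns per pixel (> 0).
#' @slot frameInterval minutes per frame; NA for a single frame.
#' @slot gravity unit 2-vector (x, y) in image coordinates.
#' @slot meta free-form metadata list.
#' @exportClass ChannelStack
setClass("ChannelStack", representation(
  data = "array", pixelSize = "numeric", frameInterval = "numeric",
  gravity = "numeric", meta = "list"
))

setValidity("ChannelStack", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L || d[3] != 2L)
    msg <- c(msg, "data must be an ny x nx x 2 x T array")
  if (any(object@data < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be >= 0")
  if (!(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@gravity) != 2L ||
      abs(sqrt(sum(object@gravity^2)) - 1) > 1e-6)
    msg <- c(msg, "gravity must be a unit 2-vector")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelStack
#'
#' @param i488,i405 a matrix (single frame) or list of matrices (time
#'   series) of nonnegative intensities for the 488- and 405-excited
#'   channel respectively.
#' @param pixelSize microns per pixel.
#' @param frameInterval minutes between frames (NA for single frame).
#' @param gravity gravity direction in image coordinates (normalized).
#' @param meta optional metadata list.
#' @return a \code{ChannelStack}.
#' @export
channelStack <- function(i488, i405, pixelSize = 1, frameInterval = NA_real_,
                         gravity = c(0, 1), meta = list()) {
  if (is.matrix(i488)) i488 <- list(i488)
  if (is.matrix(i405)) i405 <- list(i405)
  if (length(i488) != length(i405))
    rzStop("channel frame counts differ", "structural")
  d <- dim(i488[[1]])
  ok <- all(vapply(c(i488, i405), function(m) identical(dim(m), d), logical(1)))
  if (!ok) rzStop("all frames must share dimensions across both channels",
                  "structural")
  arr <- array(0, dim = c(d[1], d[2], 2L, length(i488)),
               dimnames = list(NULL, NULL, c("488", "405"), NULL))
  for (t in seq_along(i488)) {
    arr[, , 1L, t] <- i488[[t]]
    arr[, , 2L, t] <- i405[[t]]
  }
  new("ChannelStack", data = arr, pixelSize = pixelSize,
      frameInterval = frameInterval, gravity = unitVec(gravity), meta = meta)
}

## ---------------------------------------------------------------------------
## RootGeometry
## ---------------------------------------------------------------------------

#' Per-frame spatial scaffold of a segmented root
#'
#' @slot mask logical matrix (TRUE = root).
#' @slot contour n x 2 matrix (x, y) of boundary pixel coordinates.
#' @slot midline m x 2 matrix (x, y), ordered tip first, shootward last.
#' @slot arcLengthUm cumulative arc length from the tip, per midline point.
#' @slot tip refined tip location (x, y), on the mask boundary.
#' @slot tipTangent unit vector of the root axis at the tip, pointing
#'   tipward (away from the shoot).
#' @slot pixelSize microns per pixel.
#' @exportClass RootGeometry
setClass("RootGeometry", representation(
  mask = "matrix", contour = "matrix", midline = "matrix",
  arcLengthUm = "numeric", tip = "numeric", tipTangent = "numeric",
  pixelSize = "numeric"
))

setValidity("RootGeometry", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@arcLengthUm) != nrow(object@midline))
    msg <- c(msg, "arcLengthUm must match midline length")
  if (length(object@arcLengthUm) > 1 && any(diff(object@arcLengthUm) <= 0))
    msg <- c(msg, "arc length must be strictly increasing from the tip")
  if (abs(sqrt(sum(object@tipTangent^2)) - 1) > 1e-6)
    msg <- c(msg, "tipTangent must have unit norm")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SurfaceBand
## ---------------------------------------------------------------------------

#' Surface sampling band (medium pixels 10-25 px off the root)
#'
#' Each row of \code{pixels} is one medium pixel with its Euclidean
#' distance to the root mask, longitudinal coordinate (arc length of the
#' nearest midline point, from the tip), side label, displacement from
#' the midline, and background-subtracted channel intensities.
#'
#' @slot pixels data.frame with columns x, y, distPx, sUm, side
#'   ("left"/"right"), vx, vy (displacement from nearest midline point),
#'   I488, I405.
#' @slot bandMinPx,bandMaxPx band bounds used.
#' @slot pixelSize microns per pixel.
#' @exportClass SurfaceBand
setClass("SurfaceBand", representation(
  pixels = "data.frame", bandMinPx = "numeric", bandMaxPx = "numeric",
  pixelSize = "numeric"
))

setValidity("SurfaceBand", function(object) {
  msg <- character()
  need <- c("x", "y", "distPx", "sUm", "side", "vx", "vy", "I488", "I405")
  if (!all(need %in% names(object@pixels)))
    msg <- c(msg, "pixels must have columns x,y,distPx,sUm,side,vx,vy,I488,I405")
  else {
    p <- object@pixels
    if (nrow(p)) {
      if (any(p$distPx < object@bandMinPx - 1e-9) ||
          any(p$distPx > object@bandMaxPx + 1e-9))
        msg <- c(msg, "band pixel distances outside [bandMinPx, bandMaxPx]")
      if (any(p$sUm < 0)) msg <- c(msg, "sUm must be >= 0")
      if (!all(p$side %in% c("left", "right")))
        msg <- c(msg, "side must be left/right")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PHProfile
## ---------------------------------------------------------------------------

#' Longitudinal F488/405 ratio profile
#'
#' Bin means of the excitation ratio against distance from the root tip,
#' for the left flank, the right flank and both pooled. The per-bin
#' ratio is the ratio of summed intensities (sum I488 / sum I405).
#'
#' @slot bins data.frame: positionUm (bin center), side
#'   ("left"/"right"/"both"), nPixels, meanRatio, sdRatio, pH (NA if
#'   uncalibrated), valid.
#' @slot binUm bin length in microns.
#' @slot pixelSize microns per pixel.
#' @slot calibrated logical; TRUE once a calibration curve was applied.
#' @exportClass PHProfile
setClass("PHProfile", representation(
  bins = "data.frame", binUm = "numeric", pixelSize = "numeric",
  calibrated = "logical"
))

setValidity("PHProfile", function(object) {
  msg <- character()
  b <- object@bins
  need <- c("positionUm", "side", "nPixels", "meanRatio", "sdRatio",
            "pH", "valid")
  if (!all(need %in% names(b))) {
    msg <- c(msg, "bins must have columns positionUm, side, nPixels, meanRatio, sdRatio, pH, valid")
  } else if (nrow(b)) {
    for (sd_ in unique(b$side)) {
      pos <- b$positionUm[b$side == sd_]
      if (any(diff(pos) <= 0))
        msg <- c(msg, "positions must be strictly increasing within a side")
    }
    if (any(b$meanRatio[b$valid] <= 0, na.rm = TRUE))
      msg <- c(msg, "valid bins must have positive meanRatio")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CalibrationCurve
## ---------------------------------------------------------------------------

#' Monotone mapping between F488/405 ratio and pH
#'
#' @slot standards data.frame (pH, ratio), sorted by pH, duplicates
#'   averaged; the ratio rises strictly with pH.
#' @slot model "interpolating" (monotone Hyman spline) or "sigmoid"
#'   (4-parameter logistic in ratio vs pH).
#' @slot params model parameters (sigmoid: rMin, rMax, pKa, slope).
#' @slot pHRange,ratioRange fitted domain; queries outside are clamped.
#' @slot rms residual RMS of the fit (0 for interpolating).
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", representation(
  standards = "data.frame", model = "character", params = "list",
  pHRange = "numeric", ratioRange = "numeric", rms = "numeric"
))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (!object@model %in% c("interpolating", "sigmoid"))
    msg <- c(msg, "model must be interpolating or sigmoid")
  if (nrow(object@standards) < 3)
    msg <- c(msg, "at least 3 standards required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## KineticsTrack
## ---------------------------------------------------------------------------

#' Time-resolved root geometry and surface-band track
#'
#' @slot timesMin frame times in minutes, strictly increasing.
#' @slot geoms list of RootGeometry (or NULL where segmentation failed).
#' @slot bands list of SurfaceBand (or NULL).
#' @slot ok logical vector; FALSE for flagged/interpolated frames.
#' @slot gravity unit gravity vector.
#' @slot pixelSize microns per pixel.
#' @slot config the RunConfig used.
#' @exportClass KineticsTrack
setClass("KineticsTrack", representation(
  timesMin = "numeric", geoms = "list", bands = "list", ok = "logical",
  gravity = "numeric", pixelSize = "numeric", config = "RunConfig"
))

setValidity("KineticsTrack", function(object) {
  msg <- character()
  if (length(object@timesMin) > 1 && any(diff(object@timesMin) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@geoms) != length(object@timesMin) ||
      length(object@ok) != length(object@timesMin))
    msg <- c(msg, "geoms/ok must match timesMin length")
  if (length(msg)) msg else TRUE
})
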
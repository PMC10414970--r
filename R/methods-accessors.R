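#' @describeIn nFrames frames in a ChannelStack
#' @export
setMethod("nFrames", "ChannelStack", function(x) dim(x@data)[4])

#' @describeIn nFrames frames in a KineticsTrack
#' @export
setMethod("nFrames", "KineticsTrack", function(x) length(x@timesMin))

#' @describeIn pixelSize of a ChannelStack
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixelSize)

#' @describeIn pixelSize of a RootGeometry
#' @export
setMethod("pixelSize", "RootGeometry", function(x) x@pixelSize)

#' @describeIn pixelSize of a SurfaceBand
#' @export
setMethod("pixelSize", "SurfaceBand", function(x) x@pixelSize)

#' @describeIn frameInterval of a ChannelStack
#' @export
setMethod("frameInterval", "ChannelStack", function(x) x@frameInterval)

#' @describeIn getFrame frame of a ChannelStack
#' @export
setMethod("getFrame", "ChannelStack", function(x, t = 1L) {
  if (t < 1 || t > nFrames(x)) rzStop("frame index out of range", "structural")
  list(I488 = x@data[, , 1L, t], I405 = x@data[, , 2L, t])
})

#' @describeIn bandPixels of a SurfaceBand
#' @export
setMethod("bandPixels", "SurfaceBand", function(x) x@pixels)

#' @describeIn profileBins of a PHProfile
#' @export
setMethod("profileBins", "PHProfile", function(x) x@bins)

#' @describeIn standards of a CalibrationCurve
#' @export
setMethod("standards", "CalibrationCurve", function(x) x@standards)

#' @describeIn rootMask of a RootGeometry
#' @export
setMethod("rootMask", "RootGeometry", function(x) x@mask)

#' @describeIn midline of a RootGeometry
#' @export
setMethod("midline", "RootGeometry", function(x) x@midline)

#' @describeIn tipPoint of a RootGeometry
#' @export
setMethod("tipPoint", "RootGeometry", function(x) x@tip)

#' @describeIn tipTangent of a RootGeometry
#' @export
setMethod("tipTangent", "RootGeometry", function(x) x@tipTangent)

#' @describeIn midlineLengthUm of a RootGeometry
#' @export
setMethod("midlineLengthUm", "RootGeometry",
          function(x) max(x@arcLengthUm))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChannelStack: %d frame(s), %d x %d px, channels (488, 405)\n",
              d[4], d[1], d[2]))
  cat(sprintf("  pixel size %.4g um/px; frame interval %s min; gravity (%g, %g)\n",
              object@pixelSize,
              ifelse(is.na(object@frameInterval), "NA",
                     format(object@frameInterval)),
              object@gravity[1], object@gravity[2]))
})

setMethod("show", "RootGeometry", function(object) {
  cat(sprintf("RootGeometry: mask %d x %d px, midline %d pts, length %.1f um\n",
              nrow(object@mask), ncol(object@mask), nrow(object@midline),
              max(object@arcLengthUm)))
  cat(sprintf("  tip (%.1f, %.1f) px; tangent (%.3f, %.3f)\n",
              object@tip[1], object@tip[2],
              object@tipTangent[1], object@tipTangent[2]))
})

setMethod("show", "SurfaceBand", function(object) {
  cat(sprintf("SurfaceBand: %d pixels, %g-%g px off the root, s up to %.1f um\n",
              nrow(object@pixels), object@bandMinPx, object@bandMaxPx,
              if (nrow(object@pixels)) max(object@pixels$sUm) else NA))
})

setMethod("show", "PHProfile", function(object) {
  b <- object@bins
  cat(sprintf("PHProfile: %d bins (%d valid), bin %.2f um, %s\n",
              nrow(b), sum(b$valid), object@binUm,
              if (object@calibrated) "calibrated (pH)" else "uncalibrated (ratio)"))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve (%s): %d standards, pH [%.2f, %.2f], ratio [%.3g, %.3g], rms %.3g\n",
              object@model, nrow(object@standards),
              object@pHRange[1], object@pHRange[2],
              object@ratioRange[1], object@ratioRange[2], object@rms))
})

setMethod("show", "KineticsTrack", function(object) {
  cat(sprintf("KineticsTrack: %d frames over %.1f min (%d ok)\n",
              length(object@timesMin), diff(range(object@timesMin)),
              sum(object@ok)))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: band %g-%g px, bins %g px, backgrounds (%g, %g), nMin %g\n",
              object@bandMinPx, object@bandMaxPx, object@binLengthPx,
              object@background488, object@background405, object@nMinPixels))
})
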
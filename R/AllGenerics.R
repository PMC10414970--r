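#' Number of frames in a stack or track
#' @param x a \code{ChannelStack} or \code{KineticsTrack}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Pixel size in microns per pixel
#' @param x an object carrying spatial metadata.
#' @return numeric scalar, microns per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Frame interval in minutes
#' @param x a \code{ChannelStack}.
#' @return numeric scalar (NA for single frames).
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Extract one two-channel frame
#' @param x a \code{ChannelStack}.
#' @param t frame index.
#' @return list with matrices \code{I488} and \code{I405}.
#' @export
setGeneric("getFrame", function(x, t = 1L) standardGeneric("getFrame"))

#' Band pixel table
#' @param x a \code{SurfaceBand}.
#' @return the pixel data.frame.
#' @export
setGeneric("bandPixels", function(x) standardGeneric("bandPixels"))

#' Profile bin table
#' @param x a \code{PHProfile}.
#' @return the bin data.frame.
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' Calibration standards
#' @param x a \code{CalibrationCurve}.
#' @return data.frame of (pH, ratio) standards.
#' @export
setGeneric("standards", function(x) standardGeneric("standards"))

#' Root mask
#' @param x a \code{RootGeometry}.
#' @return logical matrix, TRUE on the root.
#' @export
setGeneric("rootMask", function(x) standardGeneric("rootMask"))

#' Midline point sequence (tip first)
#' @param x a \code{RootGeometry}.
#' @return m x 2 matrix of (x, y) coordinates.
#' @export
setGeneric("midline", function(x) standardGeneric("midline"))

#' Tip location
#' @param x a \code{RootGeometry}.
#' @return numeric (x, y).
#' @export
setGeneric("tipPoint", function(x) standardGeneric("tipPoint"))

#' Tip tangent (unit vector, pointing tipward)
#' @param x a \code{RootGeometry}.
#' @return numeric (x, y).
#' @export
setGeneric("tipTangent", function(x) standardGeneric("tipTangent"))

#' Midline length in microns (tip to shootward end)
#' @param x a \code{RootGeometry}.
#' @return numeric scalar.
#' @export
setGeneric("midlineLengthUm", function(x) standardGeneric("midlineLengthUm"))
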
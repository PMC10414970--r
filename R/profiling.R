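## Longitudinal profiles: band pixels -> binned F488/405 ratio curves.
## The per-bin ratio is sum(I488)/sum(I405) over the bin's pixels, not
## the mean of per-pixel ratios: per-pixel ratios are noise-amplifying
## and biased at low counts, whereas the ratio of sums matches binning
## the fluorescence intensity of both channels first.

#' Bin a surface band into a longitudinal ratio profile
#'
#' Pixels are grouped into half-open longitudinal bins of
#' \code{binLengthPx} pixels of arc length along the midline (default 20
#' px; together with the default 15 px band width this reproduces
#' 15 x 20 px bins). Profiles are produced per side and for both sides
#' pooled, and truncated at \code{maxDistUm}. Bins with fewer than
#' \code{nMinPixels} pixels or with a vanishing 405 sum are marked
#' invalid.
#'
#' @param band a \code{SurfaceBand}.
#' @param config a \code{RunConfig}.
#' @param curve optional \code{CalibrationCurve}; if given, bin ratios
#'   are converted to pH (bin ratios are calibrated, never re-averaged
#'   calibrated pH).
#' @return a \code{PHProfile} with sides "left", "right" and "both".
#' @export
binProfile <- function(band, config = runConfig(), curve = NULL) {
  p <- bandPixels(band)
  if (!nrow(p)) rzStop("empty band: no profile", "empty_profile")
  binUm <- config@binLengthPx * band@pixelSize
  binId <- floor(p$sUm / binUm)
  ## pixels beyond the midline end clamp to its last point, so max(sUm)
  ## equals the measurable midline extent; bins not fully inside it mix
  ## border geometry and are marked invalid
  maxS <- max(p$sUm)
  mkSide <- function(rows, label) {
    if (!length(rows)) return(NULL)
    b <- binId[rows]
    s488 <- tapply(p$I488[rows], b, sum)
    s405 <- tapply(p$I405[rows], b, sum)
    n <- tapply(rows, b, length)
    ids <- as.numeric(names(s488))
    ratio <- ifelse(s405 > 0, s488 / s405, NA_real_)
    ## descriptive spread of per-pixel ratios inside the bin
    okPix <- p$I405[rows] > 0
    rr <- ifelse(okPix, p$I488[rows] / pmax(p$I405[rows], 1e-300), NA_real_)
    sdr <- tapply(rr, b, stats::sd, na.rm = TRUE)
    floorVal <- config@ratioFloor * max(s405)
    valid <- as.numeric(n) >= config@nMinPixels & s405 > floorVal &
      !is.na(ratio) & ratio > 0 & (ids + 1) * binUm <= maxS + 1e-9
    data.frame(positionUm = (ids + 0.5) * binUm, side = label,
               nPixels = as.integer(n), meanRatio = as.numeric(ratio),
               sdRatio = as.numeric(sdr), pH = NA_real_,
               valid = as.logical(valid), stringsAsFactors = FALSE)
  }
  parts <- list(mkSide(which(p$side == "left"), "left"),
                mkSide(which(p$side == "right"), "right"),
                mkSide(seq_len(nrow(p)), "both"))
  bins <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  bins <- bins[bins$positionUm <= config@maxDistUm, , drop = FALSE]
  bins <- bins[order(match(bins$side, c("left", "right", "both")),
                     bins$positionUm), , drop = FALSE]
  rownames(bins) <- NULL
  prof <- new("PHProfile", bins = bins, binUm = binUm,
              pixelSize = band@pixelSize, calibrated = FALSE)
  if (!is.null(curve)) prof <- calibrateProfile(prof, curve)
  prof
}

#' Per-pixel F488/405 ratio image
#'
#' @param i488,i405 channel matrices of one frame.
#' @param config a \code{RunConfig} (per-channel backgrounds).
#' @return matrix of ratios; pixels whose background-subtracted 405
#'   denominator is <= 0 are NA (their count is logged).
#' @export
ratioImage <- function(i488, i405, config = runConfig()) {
  if (!identical(dim(i488), dim(i405)))
    rzStop("channel dimensions differ", "structural")
  num <- i488 - config@background488
  den <- i405 - config@background405
  bad <- den <= 0
  if (any(bad)) rzLog(sprintf("masked %d pixels with nonpositive denominator",
                              sum(bad)))
  out <- num / den
  out[bad] <- NA_real_
  out
}

## Bilinear interpolation of image values at fractional (x, y).
bilinearAt <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), nx - 1); y0 <- pmin(pmax(floor(y), 1), ny - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x0 + 1)]
  v10 <- img[cbind(y0 + 1, x0)]; v11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Binned intensity profile along a polyline
#'
#' Samples the image at 1 px steps along the polyline (bilinear
#' interpolation) and averages the samples in half-open bins of
#' \code{binUm} microns of polyline arc length (default 10 um, the
#' convention for epidermal cell-file intensity profiles).
#'
#' @param image 2D numeric matrix.
#' @param polyline k x 2 (x, y) matrix, at least 2 points, inside the image.
#' @param binUm bin length in microns.
#' @param pixelSize microns per pixel.
#' @return data.frame (positionUm, meanIntensity).
#' @export
lineProfileBinning <- function(image, polyline, binUm = 10, pixelSize = 1) {
  if (nrow(polyline) < 2)
    rzStop("polyline needs at least 2 points", "structural")
  if (any(polyline[, 1] < 1 | polyline[, 1] > ncol(image) |
          polyline[, 2] < 1 | polyline[, 2] > nrow(image)))
    rzStop("polyline outside image bounds", "out_of_bounds")
  ## resample at ~1 px spacing
  seglen <- sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  sPx <- seq(0, total, by = 1)
  xs <- stats::approx(cum, polyline[, 1], xout = sPx)$y
  ys <- stats::approx(cum, polyline[, 2], xout = sPx)$y
  vals <- bilinearAt(image, xs, ys)
  sUm <- sPx * pixelSize
  binId <- floor(sUm / binUm)
  agg <- tapply(vals, binId, mean)
  ids <- as.numeric(names(agg))
  data.frame(positionUm = (ids + 0.5) * binUm,
             meanIntensity = as.numeric(agg))
}

## Values of a profile (one side) on a position grid; exact at matching
## bin centers, linear interpolation otherwise, NA outside.
profileValuesOnGrid <- function(profile, grid, side = "both") {
  b <- profileBins(profile)
  b <- b[b$side == side & b$valid, , drop = FALSE]
  col <- if (profile@calibrated) "pH" else "meanRatio"
  if (nrow(b) < 2) return(rep(NA_real_, length(grid)))
  stats::approx(b$positionUm, b[[col]], xout = grid, rule = 1)$y
}
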
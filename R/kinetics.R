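## Time-series analysis: per-frame geometry tracking, elongation rate,
## tip-angle dynamics, lower/upper flank asymmetry during
## gravistimulation, and fast surface-pH oscillation traces.

#' Track root geometry through a time series
#'
#' Segments every frame independently, extracts geometry and the surface
#' band, and guards tip correspondence between consecutive frames (a tip
#' jump beyond \code{maxJumpUm} flags the frame). Flagged frames are
#' tolerated and interpolated over by the derived-series functions; more
#' than 2 consecutive failures abort.
#'
#' @param stack a \code{ChannelStack} with >= 2 frames.
#' @param config a \code{RunConfig}.
#' @param maxJumpUm maximum credible tip displacement between frames.
#' @return a \code{KineticsTrack}.
#' @export
trackRoot <- function(stack, config = runConfig(), maxJumpUm = 100) {
  nT <- nFrames(stack)
  if (nT < 2) rzStop("tracking needs at least 2 frames", "structural")
  if (is.na(frameInterval(stack)))
    rzStop("stack has no frame interval", "structural")
  times <- (seq_len(nT) - 1) * frameInterval(stack)
  geoms <- vector("list", nT)
  bands <- vector("list", nT)
  ok <- logical(nT)
  lastTip <- NULL
  consecFail <- 0
  for (t in seq_len(nT)) {
    fr <- getFrame(stack, t)
    res <- tryCatch({
      g <- rootGeometry(fr$I488, fr$I405, config, pixelSize(stack),
                        stack@gravity)
      b <- extractSurfaceBand(g, fr$I488, fr$I405, config)
      list(g = g, b = b)
    }, rhizopH_error = function(e) e)
    if (inherits(res, "condition")) {
      ok[t] <- FALSE
    } else {
      jump <- if (is.null(lastTip)) 0 else
        sqrt(sum((res$g@tip - lastTip)^2)) * pixelSize(stack)
      if (jump > maxJumpUm) {
        ok[t] <- FALSE
        rzLog(sprintf("frame %d: tip jump %.1f um exceeds guard", t, jump))
      } else {
        geoms[[t]] <- res$g
        bands[[t]] <- res$b
        ok[t] <- TRUE
        lastTip <- res$g@tip
      }
    }
    consecFail <- if (ok[t]) 0 else consecFail + 1
    if (consecFail > 2)
      rzStop(sprintf("tracking lost: %d consecutive unsegmentable frames",
                     consecFail), "tracking_lost")
  }
  new("KineticsTrack", timesMin = times, geoms = geoms, bands = bands,
      ok = ok, gravity = stack@gravity, pixelSize = pixelSize(stack),
      config = config)
}

## Per-frame scalar with linear interpolation across flagged frames.
interpOverFlagged <- function(times, values, ok) {
  if (all(ok)) return(values)
  if (sum(ok) < 2) rzStop("too few valid frames", "tracking_lost")
  out <- values
  out[!ok] <- stats::approx(times[ok], values[ok], xout = times[!ok],
                            rule = 2)$y
  out
}

#' Root elongation rate
#'
#' Total midline length increment between the first and last frame
#' divided by the elapsed minutes. The midline runs from the field
#' border (the fixed shootward anchor) to the tip, so its length
#' increment is the root length increment.
#'
#' @param track a \code{KineticsTrack}.
#' @return elongation rate in um/min (attribute \code{"lengthsUm"}
#'   carries the per-frame lengths).
#' @export
elongationRate <- function(track) {
  lens <- vapply(seq_along(track@geoms), function(t)
    if (track@ok[t]) midlineLengthUm(track@geoms[[t]]) else NA_real_,
    numeric(1))
  lens <- interpOverFlagged(track@timesMin, lens, track@ok & !is.na(lens))
  n <- length(lens)
  inc <- lens[n] - lens[1]
  if (inc < -0.05 * lens[1])
    rzWarn(sprintf("root length decreased by %.1f um: registration failure?",
                   -inc), class = "registration")
  rate <- inc / (track@timesMin[n] - track@timesMin[1])
  attr(rate, "lengthsUm") <- lens
  rate
}

#' Tip angle time series
#'
#' Unsigned angle between the tip tangent and the gravity vector, per
#' frame, in degrees. Under the gravistimulation convention a freshly
#' rotated root starts near 90 degrees and approaches 0 as it realigns.
#'
#' @param track a \code{KineticsTrack}.
#' @param smooth apply a centered 3-frame running median (default TRUE).
#' @return data.frame (timeMin, angleDeg).
#' @export
tipAngleSeries <- function(track, smooth = TRUE) {
  ang <- vapply(seq_along(track@geoms), function(t)
    if (track@ok[t])
      vecAngleDeg(track@geoms[[t]]@tipTangent, track@gravity)
    else NA_real_, numeric(1))
  ang <- interpOverFlagged(track@timesMin, ang, track@ok & !is.na(ang))
  if (smooth && length(ang) >= 3)
    ang <- stats::runmed(ang, 3, endrule = "keep")
  data.frame(timeMin = track@timesMin, angleDeg = as.numeric(ang))
}

#' Lower/upper flank ratio series in a longitudinal window
#'
#' Band pixels within \code{windowUm} of the tip are split into the
#' lower and upper flank by the sign of their displacement from the
#' midline projected on the gravity vector; each flank's mean F488/405
#' ratio (ratio of sums) and the lower/upper quotient are reported per
#' frame. For vertical sessions use [oscillationTrace()] (left/right)
#' instead: the gravity projection degenerates when the root is aligned
#' with gravity.
#'
#' @param track a \code{KineticsTrack}.
#' @param windowUm c(lo, hi) distance-from-tip window, default the
#'   transition-zone region 200-500 um.
#' @return data.frame (timeMin, lowerMeanRatio, upperMeanRatio,
#'   lowerOverUpper, flagged).
#' @export
flankRatioSeries <- function(track, windowUm = c(200, 500)) {
  g <- track@gravity
  rows <- lapply(seq_along(track@bands), function(t) {
    if (!track@ok[t])
      return(data.frame(timeMin = track@timesMin[t],
                        lowerMeanRatio = NA_real_, upperMeanRatio = NA_real_,
                        lowerOverUpper = NA_real_, flagged = TRUE))
    p <- bandPixels(track@bands[[t]])
    if (max(p$sUm) < windowUm[1])
      rzStop(sprintf("window [%g, %g] um lies beyond the root extent (%.0f um)",
                     windowUm[1], windowUm[2], max(p$sUm)), "window")
    p <- p[p$sUm >= windowUm[1] & p$sUm <= windowUm[2], , drop = FALSE]
    proj <- p$vx * g[1] + p$vy * g[2]
    lower <- p[proj > 0, , drop = FALSE]
    upper <- p[proj < 0, , drop = FALSE]
    if (!nrow(lower) || !nrow(upper) || sum(lower$I405) <= 0 ||
        sum(upper$I405) <= 0)
      return(data.frame(timeMin = track@timesMin[t],
                        lowerMeanRatio = NA_real_, upperMeanRatio = NA_real_,
                        lowerOverUpper = NA_real_, flagged = TRUE))
    lo <- sum(lower$I488) / sum(lower$I405)
    up <- sum(upper$I488) / sum(upper$I405)
    data.frame(timeMin = track@timesMin[t], lowerMeanRatio = lo,
               upperMeanRatio = up, lowerOverUpper = lo / up,
               flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "windowUm") <- windowUm
  out
}

#' Detect the onset of lower-flank alkalinization
#'
#' First frame at which the lower/upper ratio exceeds
#' \code{1 + k * sd(pre-stimulus ratios)} for \code{nConsecutive}
#' consecutive frames.
#'
#' @param flankSeries output of [flankRatioSeries()].
#' @param nBaseline number of leading frames treated as pre-stimulus.
#' @param k threshold multiplier on the pre-stimulus SD (default 3).
#' @param nConsecutive consecutive frames required above threshold.
#' @return list(frame, timeMin, threshold); frame is NA when no onset is
#'   found.
#' @export
flankOnset <- function(flankSeries, nBaseline = 3, k = 3, nConsecutive = 2) {
  r <- flankSeries$lowerOverUpper
  base <- r[seq_len(min(nBaseline, length(r)))]
  sdb <- stats::sd(base, na.rm = TRUE)
  if (!is.finite(sdb) || sdb == 0) sdb <- 1e-6
  thr <- 1 + k * sdb
  above <- !is.na(r) & r > thr
  above[seq_len(min(nBaseline, length(r)))] <- FALSE # pre-stimulus frames
  runEnd <- stats::filter(as.numeric(above), rep(1, nConsecutive),
                          sides = 1)
  hit <- which(runEnd == nConsecutive)
  if (!length(hit)) return(list(frame = NA_integer_, timeMin = NA_real_,
                                threshold = thr))
  f <- hit[1] - nConsecutive + 1L
  list(frame = as.integer(f), timeMin = flankSeries$timeMin[f],
       threshold = thr)
}

#' Surface-pH oscillation trace at high frame rate
#'
#' Uses the first frame's geometry and band (the root is assumed
#' quasi-static over a fast acquisition) and reads the windowed mean
#' ratio per frame, linearly detrends it, and reports the dominant
#' period from the periodogram peak together with its amplitude. A
#' left/right asymmetry trace is included.
#'
#' @param stack a \code{ChannelStack} with at least 64 frames at a fixed
#'   interval.
#' @param config a \code{RunConfig}.
#' @param windowUm c(lo, hi) distance-from-tip window.
#' @return list(timesMin, ratio, detrended, leftOverRight, periodMin,
#'   amplitude).
#' @export
oscillationTrace <- function(stack, config = runConfig(),
                             windowUm = c(200, 500)) {
  nT <- nFrames(stack)
  if (nT < 64)
    rzStop(sprintf("oscillation analysis needs >= 64 frames, got %d", nT),
           "insufficient_series")
  if (is.na(frameInterval(stack)))
    rzStop("stack has no frame interval", "structural")
  fr1 <- getFrame(stack, 1)
  geom <- rootGeometry(fr1$I488, fr1$I405, config, pixelSize(stack),
                       stack@gravity)
  band <- extractSurfaceBand(geom, fr1$I488, fr1$I405, config)
  p <- bandPixels(band)
  p <- p[p$sUm >= windowUm[1] & p$sUm <= windowUm[2], , drop = FALSE]
  if (!nrow(p)) rzStop("empty window", "window")
  idx <- cbind(p$y, p$x)
  left <- p$side == "left"
  times <- (seq_len(nT) - 1) * frameInterval(stack)
  ratio <- numeric(nT); lr <- numeric(nT)
  for (t in seq_len(nT)) {
    fr <- getFrame(stack, t)
    v488 <- pmax(fr$I488[idx] - config@background488, 0)
    v405 <- pmax(fr$I405[idx] - config@background405, 0)
    ratio[t] <- sum(v488) / sum(v405)
    lr[t] <- (sum(v488[left]) / sum(v405[left])) /
      (sum(v488[!left]) / sum(v405[!left]))
  }
  det <- stats::resid(stats::lm(ratio ~ times))
  ## periodogram via FFT; exclude the DC term
  n <- length(det)
  sp <- Mod(stats::fft(det))^2 / n
  ks <- seq_len(floor(n / 2))
  peak <- ks[which.max(sp[ks + 1])]
  periodMin <- n * frameInterval(stack) / peak
  amplitude <- 2 * Mod(stats::fft(det)[peak + 1]) / n
  list(timesMin = times, ratio = ratio, detrended = as.numeric(det),
       leftOverRight = lr, periodMin = periodMin, amplitude = amplitude)
}
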
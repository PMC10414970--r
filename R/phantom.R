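## Synthetic microscopy phantoms with full ground truth: a dark
## (dye-excluded) root embedded in bright stained medium, a programmed
## longitudinal surface-pH field, forward ratiometric optics, shared
## multiplicative illumination, Poisson + Gaussian noise, and optional
## growth, gravitropic bending, lower-flank alkalinization and halo
## oscillation.
##
## Radial model: the surface pH holds at the programmed pH(s) out to
## `plateauPx` (default: the outer band edge, 25 px) and relaxes
## exponentially to the medium pH beyond, so the sampled band reads the
## programmed profile directly while the image still shows a decaying
## halo.

#' Specify a synthetic root phantom
#'
#' Defaults emulate the study conditions of the imaging protocol this
#' package targets: 0.65 um/px, a ~620 um root entering from the top of
#' a 1024 x 256 px field, acidic baseline surface pH 5.2 with a Gaussian
#' alkaline halo (center 350 um from the tip, amplitude +0.5 pH, sigma
#' 60 um) over medium at pH 5.7, a logistic forward ratio curve with
#' midpoint pKa 6.4 spanning roughly a 4-fold ratio change over pH
#' 4.5-6.0, mean medium counts ~300 per channel, Poisson noise plus
#' Gaussian read noise (sd 3 counts).
#'
#' @param imageSize c(ny, nx) in px.
#' @param pixelSize um per px.
#' @param rootLengthPx,rootRadiusPx,taperPx straight-root geometry: total
#'   length, maximum half-width, and tip taper length (the radius grows
#'   as sqrt(s/taper) up to its maximum).
#' @param angleDeg initial angle between the tipward root axis and the
#'   gravity vector (0 = growing straight down, 90 = horizontal +x).
#' @param entryPx optional (x, y) border entry point; chosen from the
#'   angle when NULL.
#' @param mediumPH pH of the bulk stained medium.
#' @param baselinePH,halo surface pH model: baseline plus a Gaussian
#'   alkaline halo \code{list(centerUm, amplitudePH, sigmaUm)}.
#' @param pHFun optional \code{function(sUm, tMin)} overriding the
#'   baseline+halo surface pH model.
#' @param plateauPx,decayPx radial extent of the surface pH (constant out
#'   to plateauPx, exponential decay with decayPx beyond).
#' @param curve forward optics: logistic parameters
#'   \code{list(pKa, rMin, rMax, slope)}.
#' @param gain488,gain405 mean medium photon counts per channel at
#'   f-function value 1.
#' @param rootIntensity mean counts inside the (unstained) root.
#' @param background488,background405 additive per-channel offsets.
#' @param illumination optional \code{function(x, y)} multiplicative
#'   field shared by both channels (vectorized over px coordinates).
#' @param noisePoisson apply Poisson noise to pre-read counts.
#' @param readNoiseSd Gaussian read noise sd, counts.
#' @param nFrames,frameIntervalMin time series length and spacing.
#' @param growthPxPerFrame tip advance per frame, px.
#' @param bendingDegPerMin,bendStartMin,pivotFromTipPx gravitropic
#'   bending: angular rate, onset time, and the fixed pivot's distance
#'   from the initial tip.
#' @param flankDeltaPH,flankOnsetMin,flankWindowUm lower-flank pH offset
#'   applied from the onset time within the longitudinal window.
#' @param oscAmplitudePH,oscPeriodMin sinusoidal modulation of the halo
#'   amplitude.
#' @param calibRangePH admissible programmed pH range (spec error
#'   outside).
#' @param seed integer; fixes every random draw (bit-reproducible).
#' @return a validated phantom spec (list, class
#'   \code{"rhizopH_phantom_spec"}).
#' @export
phantomSpec <- function(imageSize = c(1024L, 256L), pixelSize = 0.65,
                        rootLengthPx = 960, rootRadiusPx = 25, taperPx = 60,
                        angleDeg = 0, entryPx = NULL,
                        mediumPH = 5.7, baselinePH = 5.2,
                        halo = list(centerUm = 350, amplitudePH = 0.5,
                                    sigmaUm = 60),
                        pHFun = NULL, plateauPx = 25, decayPx = 30,
                        curve = list(pKa = 6.4, rMin = 0.3, rMax = 4.0,
                                     slope = 1),
                        gain488 = 300, gain405 = 300, rootIntensity = 2,
                        background488 = 0, background405 = 0,
                        illumination = NULL, noisePoisson = TRUE,
                        readNoiseSd = 3,
                        nFrames = 1L, frameIntervalMin = NA_real_,
                        growthPxPerFrame = 0,
                        bendingDegPerMin = 0, bendStartMin = 0,
                        pivotFromTipPx = 300,
                        flankDeltaPH = 0, flankOnsetMin = Inf,
                        flankWindowUm = c(200, 500),
                        oscAmplitudePH = 0, oscPeriodMin = NA_real_,
                        calibRangePH = c(4, 8), seed = 1L) {
  spec <- as.list(environment())
  if (any(!is.finite(c(rootLengthPx, rootRadiusPx, growthPxPerFrame,
                       bendingDegPerMin))))
    rzStop("phantom rates and dimensions must be finite", "spec")
  if (nFrames > 1 && is.na(frameIntervalMin))
    rzStop("time series need a frame interval", "spec")
  if (is.null(pHFun)) {
    phs <- c(mediumPH, baselinePH, baselinePH + halo$amplitudePH,
             baselinePH + halo$amplitudePH + abs(flankDeltaPH) +
               abs(oscAmplitudePH))
    if (any(phs < calibRangePH[1] | phs > calibRangePH[2]))
      rzStop("programmed pH outside the admissible calibration range", "spec")
  }
  if (is.null(entryPx)) {
    spec$entryPx <- if (abs(angleDeg) < 45)
      c(round(imageSize[2] / 2), 1) else c(1, round(imageSize[1] * 0.35))
  }
  class(spec) <- "rhizopH_phantom_spec"
  spec
}

## Tipward unit direction for an angle from gravity-down, degrees.
dirFromAngle <- function(a) c(sin(a * pi / 180), cos(a * pi / 180))

## Centerline for frame t, base -> tip, ~1 px spacing.
## Returns list(points, tipAngleDeg, lengthPx).
phantomCenterline <- function(spec, t) {
  tMin <- if (is.na(spec$frameIntervalMin)) 0 else
    (t - 1) * spec$frameIntervalMin
  bend <- spec$bendingDegPerMin * max(0, tMin - spec$bendStartMin)
  aT <- spec$angleDeg + bend
  lenT <- spec$rootLengthPx + spec$growthPxPerFrame * (t - 1)
  u0 <- dirFromAngle(spec$angleDeg)
  uT <- dirFromAngle(aT)
  E <- spec$entryPx
  Lprox <- max(0, spec$rootLengthPx - spec$pivotFromTipPx)
  Ldist <- lenT - Lprox
  sProx <- seq(0, Lprox, by = 1)
  prox <- cbind(E[1] + u0[1] * sProx, E[2] + u0[2] * sProx)
  P <- prox[nrow(prox), ]
  sDist <- seq(1, Ldist, by = 1)
  dist <- cbind(P[1] + uT[1] * sDist, P[2] + uT[2] * sDist)
  pts <- rbind(prox, dist)
  ny <- spec$imageSize[1]; nx <- spec$imageSize[2]
  marg <- spec$rootRadiusPx + 1
  if (any(pts[, 1] < 1 - marg + spec$rootRadiusPx |
          pts[, 1] > nx + marg - spec$rootRadiusPx |
          pts[, 2] < 1 - marg + spec$rootRadiusPx |
          pts[, 2] > ny + marg - spec$rootRadiusPx)) {
    need <- c(ceiling(max(pts[, 2]) + marg), ceiling(max(pts[, 1]) + marg))
    rzStop(sprintf(
      "phantom root leaves the field; suggest imageSize >= c(%d, %d)",
      need[1], need[2]), "spec")
  }
  list(points = pts, tipAngleDeg = abs(aT) %% 360, lengthPx = lenT)
}

## Rasterize the root mask by stamping discs along the centerline.
phantomMask <- function(spec, ctl) {
  ny <- spec$imageSize[1]; nx <- spec$imageSize[2]
  mask <- matrix(FALSE, ny, nx)
  pts <- ctl$points
  n <- nrow(pts)
  sFromTip <- (n - seq_len(n)) # px, approx (1 px spacing)
  rad <- spec$rootRadiusPx * sqrt(pmin(1, sFromTip / spec$taperPx))
  for (i in seq_len(n)) {
    r <- rad[i]
    if (r < 0.5) next
    x0 <- pts[i, 1]; y0 <- pts[i, 2]
    xs <- max(1, floor(x0 - r)):min(nx, ceiling(x0 + r))
    ys <- max(1, floor(y0 - r)):min(ny, ceiling(y0 + r))
    if (!length(xs) || !length(ys)) next
    dx2 <- (xs - x0)^2
    dy2 <- (ys - y0)^2
    disc <- outer(dy2, dx2, "+") <= r^2
    mask[ys, xs] <- mask[ys, xs] | disc
  }
  mask
}

## Default surface pH model: baseline + Gaussian halo (amplitude can be
## modulated in time by the oscillation term).
phantomPHFun <- function(spec) {
  if (!is.null(spec$pHFun)) return(spec$pHFun)
  function(sUm, tMin) {
    amp <- spec$halo$amplitudePH
    if (spec$oscAmplitudePH != 0 && !is.na(spec$oscPeriodMin))
      amp <- amp + spec$oscAmplitudePH *
        sin(2 * pi * tMin / spec$oscPeriodMin)
    spec$baselinePH + amp *
      exp(-(sUm - spec$halo$centerUm)^2 / (2 * spec$halo$sigmaUm^2))
  }
}

#' Render a phantom stack with ground truth
#'
#' Renders every frame of the spec (geometry, surface pH field, forward
#' optics, illumination, noise) and returns the stack together with the
#' ground truth a validation test needs: per-frame masks, centerlines
#' (tip first), tip positions, true tip angles and root lengths, and the
#' programmed pH function.
#'
#' Identical spec + seed gives bit-identical stacks; intensities are
#' snapped to the float32 grid so saved stacks round-trip exactly.
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{stack} (a \code{ChannelStack}) and
#'   \code{truth} (list: masks, centerlines, tipPx, tipAngleDeg,
#'   lengthUm, pHFun, curve, spec).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "rhizopH_phantom_spec"))
  withSeed(spec$seed, {
    ny <- spec$imageSize[1]; nx <- spec$imageSize[2]
    pHf <- phantomPHFun(spec)
    cv <- spec$curve
    L <- if (is.null(spec$illumination)) NULL else {
      outer(seq_len(ny), seq_len(nx),
            function(y, x) spec$illumination(x, y))
    }
    geomStatic <- spec$growthPxPerFrame == 0 && spec$bendingDegPerMin == 0
    i488 <- vector("list", spec$nFrames)
    i405 <- vector("list", spec$nFrames)
    masks <- vector("list", spec$nFrames)
    ctls <- vector("list", spec$nFrames)
    tips <- vector("list", spec$nFrames)
    angles <- numeric(spec$nFrames)
    lens <- numeric(spec$nFrames)
    cache <- NULL
    for (t in seq_len(spec$nFrames)) {
      tMin <- if (is.na(spec$frameIntervalMin)) 0 else
        (t - 1) * spec$frameIntervalMin
      if (is.null(cache) || !geomStatic) {
        ctl <- phantomCenterline(spec, t)
        mask <- phantomMask(spec, ctl)
        D <- EBImage::distmap((!mask) * 1)
        cutoff <- spec$plateauPx + 4 * spec$decayPx
        selIdx <- which(!mask & D <= cutoff, arr.ind = TRUE)
        ## tip-first centerline for longitudinal coordinates
        ctip <- ctl$points[rev(seq_len(nrow(ctl$points))), , drop = FALSE]
        arcPx <- c(0, cumsum(sqrt(diff(ctip[, 1])^2 + diff(ctip[, 2])^2)))
        mi <- nearestMidlineIndex(selIdx[, 2], selIdx[, 1], ctip)
        sUm <- arcPx[mi] * spec$pixelSize
        vx <- selIdx[, 2] - ctip[mi, 1]
        vy <- selIdx[, 1] - ctip[mi, 2]
        dSel <- D[selIdx]
        w <- ifelse(dSel <= spec$plateauPx, 1,
                    exp(-(dSel - spec$plateauPx) / spec$decayPx))
        cache <- list(ctl = ctl, mask = mask, selIdx = selIdx, sUm = sUm,
                      vx = vx, vy = vy, w = w, ctip = ctip)
      }
      ctl <- cache$ctl; mask <- cache$mask
      pHs <- pHf(cache$sUm, tMin)
      if (spec$flankDeltaPH != 0 && tMin >= spec$flankOnsetMin) {
        lower <- (cache$vx * 0 + cache$vy * 1) > 0 # gravity (0,1)
        inWin <- cache$sUm >= spec$flankWindowUm[1] &
          cache$sUm <= spec$flankWindowUm[2]
        pHs <- pHs + spec$flankDeltaPH * (lower & inWin)
      }
      pH <- spec$mediumPH + cache$w * (pHs - spec$mediumPH)
      r <- logistic4(pH, cv$rMin, cv$rMax, cv$pKa, cv$slope)
      f405 <- 2 / (1 + r)
      f488 <- r * f405
      rBulk <- logistic4(spec$mediumPH, cv$rMin, cv$rMax, cv$pKa, cv$slope)
      lam405 <- matrix(spec$gain405 * 2 / (1 + rBulk), ny, nx)
      lam488 <- matrix(spec$gain488 * rBulk * 2 / (1 + rBulk), ny, nx)
      lam405[cache$selIdx] <- spec$gain405 * f405
      lam488[cache$selIdx] <- spec$gain488 * f488
      lam405[mask] <- spec$rootIntensity
      lam488[mask] <- spec$rootIntensity
      if (!is.null(L)) {
        lam405 <- lam405 * L
        lam488 <- lam488 * L
      }
      noisy <- function(lam) {
        v <- if (spec$noisePoisson)
          stats::rpois(length(lam), lam) else as.numeric(lam)
        if (spec$readNoiseSd > 0)
          v <- v + stats::rnorm(length(lam), 0, spec$readNoiseSd)
        v <- v + 0 # keep double
        v[v < 0] <- 0
        m <- matrix(asFloat32(v), nrow(lam), ncol(lam))
        m
      }
      i488[[t]] <- noisy(lam488 + spec$background488)
      i405[[t]] <- noisy(lam405 + spec$background405)
      masks[[t]] <- mask
      ctls[[t]] <- cache$ctip
      tips[[t]] <- as.numeric(cache$ctip[1, ])
      angles[t] <- ctl$tipAngleDeg
      lens[t] <- ctl$lengthPx * spec$pixelSize
    }
    stack <- channelStack(i488, i405, pixelSize = spec$pixelSize,
                          frameInterval = spec$frameIntervalMin,
                          gravity = c(0, 1),
                          meta = list(source = "rhizopH-phantom"))
    list(stack = stack,
         truth = list(masks = masks, centerlines = ctls, tipPx = tips,
                      tipAngleDeg = angles, lengthUm = lens,
                      pHFun = phantomPHFun(spec), curve = spec$curve,
                      spec = spec))
  })
}

#' Render a gravitropic time series phantom
#'
#' Convenience wrapper around [makePhantom()] preconfigured for the
#' gravistimulation protocol: a horizontal root (initial tip angle 90
#' degrees), frames every 2 min for 42 min, optional programmed bending
#' about a fixed elongation-zone pivot and lower-flank alkalinization.
#'
#' @param ... overrides passed to [phantomSpec()].
#' @return as [makePhantom()].
#' @export
makeGravitropicSeries <- function(...) {
  args <- list(...)
  defaults <- list(angleDeg = 90, nFrames = 22L, frameIntervalMin = 2,
                   imageSize = c(768L, 896L), rootLengthPx = 700,
                   pivotFromTipPx = 350)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  spec <- do.call(phantomSpec, args)
  if (spec$nFrames < 2)
    rzStop("a gravitropic series needs at least 2 frames", "spec")
  makePhantom(spec)
}

#' Generate synthetic calibration standards
#'
#' Evaluates a forward logistic ratio curve on a pH grid, with optional
#' multiplicative Gaussian noise on the ratios.
#'
#' @param curve logistic parameters \code{list(pKa, rMin, rMax, slope)}.
#' @param pHGrid pH values (the standard media grid 4.5, 5.0, 5.5, 6.0
#'   by default).
#' @param noiseSd multiplicative noise fraction (0.02 = 2 percent).
#' @param seed integer seed.
#' @return data.frame (pH, ratio).
#' @export
makeCalibrationStandards <- function(curve = list(pKa = 6.4, rMin = 0.3,
                                                  rMax = 4.0, slope = 1),
                                     pHGrid = c(4.5, 5.0, 5.5, 6.0),
                                     noiseSd = 0, seed = 1L) {
  withSeed(seed, {
    r <- logistic4(pHGrid, curve$rMin, curve$rMax, curve$pKa, curve$slope)
    if (noiseSd > 0) r <- r * (1 + stats::rnorm(length(r), 0, noiseSd))
    data.frame(pH = pHGrid, ratio = r)
  })
}

#' Interpolating calibration curve matching a phantom's forward optics
#'
#' Fits the default interpolating model to noise-free standards sampled
#' from the phantom's forward curve, for closed-loop pH recovery tests.
#'
#' @param spec a [phantomSpec()].
#' @param pHGrid grid of standards to sample.
#' @return a \code{CalibrationCurve}.
#' @export
phantomCalibration <- function(spec, pHGrid = seq(4.0, 7.5, by = 0.25)) {
  std <- makeCalibrationStandards(spec$curve, pHGrid, noiseSd = 0,
                                  seed = spec$seed)
  fitCalibration(std, "interpolating")
}

#' Write a phantom spec to YAML
#' @param spec a [phantomSpec()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
savePhantomSpec <- function(spec, path) {
  s <- unclass(spec)
  s$pHFun <- NULL
  s$illumination <- NULL
  yaml::write_yaml(s, path)
  invisible(path)
}

#' Read a phantom spec from YAML
#' @param path YAML path.
#' @return a [phantomSpec()].
#' @export
loadPhantomSpec <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  y <- yaml::read_yaml(path)
  known <- names(formals(phantomSpec))
  y <- y[intersect(names(y), known)]
  if (!is.null(y$imageSize)) y$imageSize <- as.integer(unlist(y$imageSize))
  do.call(phantomSpec, y)
}
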
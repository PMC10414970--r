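## Shared fixtures, built once per test run and memoised: a default
## halo phantom plus its pipeline products, and small geometric masks.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtureEnv, inherits = FALSE))
    assign(name, make(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

## Small halo phantom (root ~300 um, halo clipped to visible range not
## needed by these tests) for fast structural checks.
tinyPhantom <- function() fixture("tiny", function() {
  makePhantom(phantomSpec(imageSize = c(256L, 96L), rootLengthPx = 200,
                          rootRadiusPx = 15, taperPx = 40, seed = 42))
})

## Mid-size phantom whose band reaches ~300 um, with its pipeline.
midPhantom <- function() fixture("mid", function() {
  makePhantom(phantomSpec(imageSize = c(512L, 160L), rootLengthPx = 460,
                          seed = 7))
})

midPipeline <- function() fixture("midpipe", function() {
  ph <- midPhantom()
  cfg <- runConfig()
  fr <- getFrame(ph$stack, 1)
  geom <- rootGeometry(fr$I488, fr$I405, cfg, pixelSize(ph$stack))
  band <- extractSurfaceBand(geom, fr$I488, fr$I405, cfg)
  list(ph = ph, cfg = cfg, fr = fr, geom = geom, band = band,
       profile = binProfile(band, cfg))
})

## Disc mask (logical) centered in an n x n field.
discMask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((xy$x - cx)^2 + (xy$y - cy)^2 <= r^2, n, n)
}

## Minimal RootGeometry wrapper for a hand-made mask (trivial midline).
geomForMask <- function(mask, pixelSize = 1) {
  new("RootGeometry", mask = mask, contour = cbind(x = 1, y = 1),
      midline = cbind(x = c(2, 2), y = c(2, 3)), arcLengthUm = c(0, 1),
      tip = c(2, 2), tipTangent = c(0, 1), pixelSize = pixelSize)
}

## Build a PHProfile directly from (position, value) vectors, for the
## statistics tests that do not need rendered images.
syntheticProfile <- function(positionUm, values, calibrated = TRUE,
                             binUm = 13, nPixels = 100L) {
  bins <- data.frame(positionUm = positionUm, side = "both",
                     nPixels = nPixels,
                     meanRatio = if (calibrated) 1 else values,
                     sdRatio = 0,
                     pH = if (calibrated) values else NA_real_,
                     valid = TRUE, stringsAsFactors = FALSE)
  new("PHProfile", bins = bins, binUm = binUm, pixelSize = 0.65,
      calibrated = calibrated)
}

## Group of synthetic profiles on a common grid: flat baseline plus an
## optional step inside a window, with per-root jitter.
syntheticGroup <- function(n, grid, delta = 0, windowUm = c(200, 500),
                           baselineSd = 0.02, noiseSd = 0.005,
                           seed = 1L) {
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    v <- 5.2 + rnorm(1, 0, baselineSd) + rnorm(length(grid), 0, noiseSd) +
      delta * (grid >= windowUm[1] & grid <= windowUm[2])
    syntheticProfile(grid, v)
  })
}
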
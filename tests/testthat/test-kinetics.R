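## Small time-series fixtures (static, growing, blanked) shared here.
staticTrack <- function() fixture("staticTrack", function() {
  ph <- makePhantom(phantomSpec(imageSize = c(320L, 120L),
                                rootLengthPx = 260, nFrames = 5L,
                                frameIntervalMin = 10, seed = 12))
  list(ph = ph, track = trackRoot(ph$stack))
})

test_that("a static phantom tracks with zero displacement and rate", {
  st <- staticTrack()
  tips <- t(vapply(st$track@geoms, function(g) g@tip, numeric(2)))
  expect_lt(max(sqrt(rowSums(sweep(tips, 2, tips[1, ])^2))), 1.5)
  expect_lt(abs(as.numeric(elongationRate(st$track))), 0.02)
})

test_that("a growing phantom recovers the programmed elongation rate", {
  ph <- makePhantom(phantomSpec(imageSize = c(400L, 120L),
                                rootLengthPx = 280, nFrames = 4L,
                                frameIntervalMin = 10,
                                growthPxPerFrame = 2, seed = 13))
  rate <- elongationRate(trackRoot(ph$stack))
  ## 2 px/frame * 0.65 um/px / 10 min = 0.13 um/min
  expect_lt(abs(as.numeric(rate) - 0.13) / 0.13, 0.1)
})

test_that("blanked frames are flagged and interpolated; 3 in a row abort", {
  st <- staticTrack()
  stack <- st$ph$stack
  blank1 <- stack
  blank1@data[, , , 3] <- 500 # uniform frame: segmentation fails
  tr <- trackRoot(blank1)
  expect_false(tr@ok[3])
  expect_true(all(tr@ok[-3]))
  ang <- tipAngleSeries(tr, smooth = FALSE)
  expect_true(all(is.finite(ang$angleDeg)))
  blank3 <- stack
  blank3@data[, , , 2:4] <- 500
  expect_error(trackRoot(blank3), class = "rhizopH_tracking_lost")
})

test_that("tip angles read 0 for vertical and 90 for horizontal roots", {
  st <- staticTrack()
  ang <- tipAngleSeries(st$track)
  expect_lt(max(abs(ang$angleDeg)), 2)
  phH <- makePhantom(phantomSpec(imageSize = c(200L, 420L),
                                 rootLengthPx = 300, angleDeg = 90,
                                 nFrames = 3L, frameIntervalMin = 2,
                                 seed = 14))
  angH <- tipAngleSeries(trackRoot(phH$stack))
  expect_true(all(abs(angH$angleDeg - 90) < 2))
})

test_that("the angle series is invariant under co-rotated gravity", {
  phH <- makePhantom(phantomSpec(imageSize = c(200L, 420L),
                                 rootLengthPx = 300, angleDeg = 90,
                                 nFrames = 3L, frameIntervalMin = 2,
                                 seed = 14))
  rot <- function(m) t(m)[, nrow(m):1]
  rotStack <- channelStack(
    lapply(1:3, function(t) rot(getFrame(phH$stack, t)$I488)),
    lapply(1:3, function(t) rot(getFrame(phH$stack, t)$I405)),
    pixelSize = 0.65, frameInterval = 2, gravity = c(-1, 0))
  a1 <- tipAngleSeries(trackRoot(phH$stack))
  a2 <- tipAngleSeries(trackRoot(rotStack))
  expect_true(all(abs(a1$angleDeg - a2$angleDeg) < 2))
})

test_that("flank ratios are symmetric without asymmetry and swap under mirroring", {
  ph <- makePhantom(phantomSpec(imageSize = c(240L, 640L),
                                rootLengthPx = 560, angleDeg = 90,
                                nFrames = 3L, frameIntervalMin = 2,
                                seed = 15))
  tr <- trackRoot(ph$stack)
  fl <- flankRatioSeries(tr, c(200, 320))
  expect_true(all(abs(fl$lowerOverUpper - 1) < 0.02))
  ## mirror about the horizontal midline axis: flanks swap exactly
  mir <- function(m) m[nrow(m):1, ]
  mirStack <- channelStack(
    lapply(1:3, function(t) mir(getFrame(ph$stack, t)$I488)),
    lapply(1:3, function(t) mir(getFrame(ph$stack, t)$I405)),
    pixelSize = 0.65, frameInterval = 2, gravity = c(0, 1))
  flM <- flankRatioSeries(trackRoot(mirStack), c(200, 320))
  expect_equal(flM$lowerMeanRatio, fl$upperMeanRatio, tolerance = 1e-6)
  expect_equal(flM$upperMeanRatio, fl$lowerMeanRatio, tolerance = 1e-6)
  ## a window beyond the root extent errors with the window in the message
  err <- tryCatch(flankRatioSeries(tr, c(900, 1200)),
                  rhizopH_window = function(e) e)
  expect_match(conditionMessage(err), "900")
})

test_that("lower-flank alkalinization onset is found within one frame", {
  ph <- makeGravitropicSeries(imageSize = c(480L, 700L), rootLengthPx = 620,
                              nFrames = 10L, flankDeltaPH = 0.4,
                              flankOnsetMin = 8, flankWindowUm = c(150, 350),
                              seed = 16)
  tr <- trackRoot(ph$stack)
  fl <- flankRatioSeries(tr, c(150, 350))
  on <- flankOnset(fl, nBaseline = 4)
  trueFrame <- 1 + 8 / 2 # onset at 8 min, 2 min/frame
  expect_lte(abs(on$frame - trueFrame), 1)
  expect_true(all(abs(fl$lowerOverUpper[seq_len(trueFrame - 1)] - 1) < 0.02))
})

test_that("oscillation traces recover the programmed period", {
  ph <- makePhantom(phantomSpec(imageSize = c(512L, 128L),
                                rootLengthPx = 450, nFrames = 72L,
                                frameIntervalMin = 1 / 12,
                                oscAmplitudePH = 0.15, oscPeriodMin = 2,
                                seed = 17))
  tr <- oscillationTrace(ph$stack, runConfig(), c(150, 280))
  expect_lt(abs(tr$periodMin - 2) / 2, 0.1)
  ## a constant series shows no comparable peak
  ph0 <- makePhantom(phantomSpec(imageSize = c(512L, 128L),
                                 rootLengthPx = 450, nFrames = 72L,
                                 frameIntervalMin = 1 / 12, seed = 17))
  tr0 <- oscillationTrace(ph0$stack, runConfig(), c(150, 280))
  expect_lt(tr0$amplitude, tr$amplitude / 10)
  ## too short a series is refused
  sub <- channelStack(
    lapply(1:10, function(t) getFrame(ph$stack, t)$I488),
    lapply(1:10, function(t) getFrame(ph$stack, t)$I405),
    pixelSize = 0.65, frameInterval = 1 / 12)
  expect_error(oscillationTrace(sub, runConfig(), c(150, 280)),
               class = "rhizopH_insufficient_series")
})
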
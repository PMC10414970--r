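## Build a SurfaceBand directly from a pixel table (profiling needs no
## image).
bandFromPixels <- function(pixels, pixelSize = 0.65) {
  new("SurfaceBand", pixels = pixels, bandMinPx = 10, bandMaxPx = 25,
      pixelSize = pixelSize)
}

uniformBand <- function(n = 4000, i488 = 200, i405 = 100, sMax = 400) {
  set.seed(3)
  data.frame(x = sample(500, n, TRUE), y = sample(500, n, TRUE),
             distPx = runif(n, 10, 25), sUm = runif(n, 0, sMax),
             side = sample(c("left", "right"), n, TRUE),
             vx = 0, vy = 0, I488 = i488, I405 = i405,
             stringsAsFactors = FALSE)
}

test_that("a uniform band gives exactly constant bin ratios", {
  band <- bandFromPixels(uniformBand())
  prof <- binProfile(band, runConfig())
  b <- profileBins(prof)
  expect_true(all(b$meanRatio[b$valid] == 2.0))
  expect_true(all(c("left", "right", "both") %in% b$side))
})

test_that("bin means are invariant to pixel order and to per-bin scaling", {
  px <- uniformBand()
  ## vary ratio across bins but keep it constant within each bin
  binUm <- 20 * 0.65
  lvl <- 1 + floor(px$sUm / binUm) %% 5
  px$I488 <- 100 * lvl
  px$I405 <- 100
  prof1 <- binProfile(bandFromPixels(px), runConfig())
  ## permutation invariance
  px2 <- px[sample(nrow(px)), ]
  prof2 <- binProfile(bandFromPixels(px2), runConfig())
  expect_equal(profileBins(prof1), profileBins(prof2))
  ## ratiometric invariance under a positive pixelwise field
  set.seed(4)
  alpha <- runif(nrow(px), 0.5, 1.5)
  px3 <- px
  px3$I488 <- px$I488 * alpha
  px3$I405 <- px$I405 * alpha
  prof3 <- binProfile(bandFromPixels(px3), runConfig())
  m <- merge(profileBins(prof1), profileBins(prof3),
             by = c("positionUm", "side"))
  expect_lt(max(abs(m$meanRatio.x / m$meanRatio.y - 1), na.rm = TRUE), 1e-6)
})

test_that("halving the bin length and re-aggregating reproduces the coarse profile", {
  px <- uniformBand()
  set.seed(5)
  px$I488 <- 100 + 50 * sin(px$sUm / 40) + rnorm(nrow(px), 0, 5)
  px$I405 <- 100 # constant denominator: count-weighted pooling is exact
  band <- bandFromPixels(px)
  coarse <- profileBins(binProfile(band, runConfig(binLengthPx = 20,
                                                   nMinPixels = 1)))
  fine <- profileBins(binProfile(band, runConfig(binLengthPx = 10,
                                                 nMinPixels = 1)))
  coarse <- coarse[coarse$side == "both", ]
  fine <- fine[fine$side == "both", ]
  binUm <- 20 * 0.65
  fine$coarseId <- floor(fine$positionUm / binUm)
  agg <- tapply(fine$meanRatio * fine$nPixels, fine$coarseId, sum) /
    tapply(fine$nPixels, fine$coarseId, sum)
  ids <- floor(coarse$positionUm / binUm)
  expect_equal(as.numeric(agg[as.character(ids)]), coarse$meanRatio,
               tolerance = 1e-12)
})

test_that("bins below the pixel floor are invalid and excluded", {
  px <- uniformBand(n = 600, sMax = 390)
  cfg <- runConfig(nMinPixels = 30)
  b <- profileBins(binProfile(bandFromPixels(px), cfg))
  small <- b$nPixels < 30
  expect_true(all(!b$valid[small]))
})

test_that("the empty band is rejected", {
  empty <- bandFromPixels(uniformBand(n = 1)[0, ])
  expect_error(binProfile(empty, runConfig()),
               class = "rhizopH_empty_profile")
})

test_that("ratio images divide pixelwise and mask degenerate denominators", {
  i405 <- matrix(runif(400, 10, 100), 20, 20)
  expect_equal(ratioImage(2 * i405, i405), matrix(2, 20, 20))
  z <- ratioImage(i405, matrix(0, 20, 20))
  expect_true(all(is.na(z)))
  ## smooth shared illumination cancels in the pixelwise ratio
  L <- outer(1:20, 1:20, function(y, x) 1 + 0.4 * sin(x / 3) * cos(y / 4))
  r1 <- ratioImage(2 * i405, i405)
  r2 <- ratioImage(2 * i405 * L, i405 * L)
  expect_lt(max(abs(r1 / r2 - 1)), 1e-6)
  expect_error(ratioImage(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "rhizopH_structural")
})

test_that("line profiles bin a ramp to its analytic means", {
  img <- matrix(7, 40, 40)
  lp <- lineProfileBinning(img, cbind(x = c(2, 38), y = c(20, 20)),
                           binUm = 10, pixelSize = 1)
  expect_true(all(lp$meanIntensity == 7))
  ## ramp I(x) = x along a horizontal line, 1 um/px, 10 um bins
  ramp <- matrix(rep(1:60, each = 1), 20, 60, byrow = TRUE)
  lp2 <- lineProfileBinning(ramp, cbind(x = c(1, 60), y = c(10, 10)),
                            binUm = 10, pixelSize = 1)
  ## bin means sit at the ramp value of the bin center +- half a pixel
  expect_true(all(abs(lp2$meanIntensity - (lp2$positionUm + 1)) <= 0.5 + 1e-9))
  expect_error(
    lineProfileBinning(ramp, cbind(x = c(-5, 10), y = c(10, 10))),
    class = "rhizopH_out_of_bounds")
})
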
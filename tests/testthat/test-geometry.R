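test_that("a two-level image segments to the exact dark rectangle", {
  img <- matrix(1000, 300, 120)
  img[41:240, 51:70] <- 10 # 20 x 200 px dark root
  mask <- segmentRoot(img / 2, img / 2, runConfig())
  truth <- matrix(FALSE, 300, 120)
  truth[41:240, 51:70] <- TRUE
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.99)
})

test_that("phantom masks are recovered with IoU >= 0.95", {
  pipe <- midPipeline()
  truth <- pipe$ph$truth$masks[[1]]
  iou <- sum(pipe$geom@mask & truth) / sum(pipe$geom@mask | truth)
  expect_gte(iou, 0.95)
})

test_that("degenerate staining is reported", {
  expect_error(segmentRoot(matrix(500, 50, 50), matrix(500, 50, 50)),
               class = "rhizopH_NoRootFound")
  bright <- matrix(1000, 80, 80)
  bright[1:5, 1:5] <- 990 # no dark object above min area
  expect_error(segmentRoot(bright, bright, runConfig()),
               class = "rhizopH_NoRootFound")
  dark <- matrix(10, 50, 50); dark[1:2, 1:2] <- 1000
  expect_error(segmentRoot(dark, dark, runConfig()),
               class = "rhizopH_staining_failure")
})

test_that("midline length matches the analytic axis of a rectangle", {
  mask <- matrix(FALSE, 460, 80)
  mask[31:430, 31:50] <- TRUE # 400 x 20 px
  ml <- extractMidline(mask, pixelSize = 0.65)
  len <- max(attr(ml, "arcLengthUm"))
  expect_lt(abs(len - 400 * 0.65) / (400 * 0.65), 0.05)
})

test_that("midline length matches a quarter-circle arc", {
  n <- 300
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  r <- sqrt((xy$x - 20)^2 + (xy$y - 20)^2)
  ang <- atan2(xy$y - 20, xy$x - 20)
  mask <- matrix(r >= 190 & r <= 210 & ang >= 0 & ang <= pi / 2, n, n)
  ml <- extractMidline(mask, pixelSize = 1)
  len <- max(attr(ml, "arcLengthUm"))
  truth <- (pi / 2) * 200
  expect_lt(abs(len - truth) / truth, 0.05)
})

test_that("a disc mask yields a degenerate midline", {
  mask <- discMask(100, 30)
  res <- tryCatch(extractMidline(mask, 1), rhizopH_error = function(e) e)
  degenerate <- inherits(res, "rhizopH_degenerate_topology") ||
    (is.matrix(res) && nrow(res) < 25)
  expect_true(degenerate)
})

test_that("tip detection follows the border and gravity rules", {
  pipe <- midPipeline()
  ## vertical root entering from the top: tip at the bottom, tangent down
  expect_equal(pipe$geom@tipTangent, c(0, 1), tolerance = 0.05)
  expect_gt(pipe$geom@tip[2], 400)
  ## rotated phantom: tangent angle to gravity within 2 degrees of truth
  ph30 <- makePhantom(phantomSpec(imageSize = c(512L, 512L),
                                  rootLengthPx = 400, angleDeg = 30,
                                  entryPx = c(120, 1), seed = 8))
  fr <- getFrame(ph30$stack, 1)
  g30 <- rootGeometry(fr$I488, fr$I405, runConfig(), 0.65)
  a <- acos(sum(g30@tipTangent * c(0, 1))) * 180 / pi
  expect_lt(abs(a - 30), 2)
  ## floating mask (neither endpoint on a border): deepest endpoint wins
  mlFloat <- cbind(x = rep(50, 60), y = 21:80)
  mask <- matrix(FALSE, 120, 100); mask[cbind(21:80, 50)] <- TRUE
  dt <- detectTip(mlFloat, mask, gravity = c(0, 1))
  expect_equal(dt$tip, c(50, 80))
  ## short midline
  expect_error(detectTip(mlFloat[1:10, ], mask, c(0, 1)),
               class = "rhizopH_short_root")
})

test_that("band pixel count on a disc matches the analytic annulus", {
  mask <- discMask(220, 50)
  geom <- geomForMask(mask)
  i <- matrix(1, 220, 220)
  band <- extractSurfaceBand(geom, i, i, runConfig())
  expected <- pi * (75^2 - 60^2)
  expect_lt(abs(nrow(bandPixels(band)) - expected) / expected, 0.03)
})

test_that("band membership equals the brute-force Euclidean distance oracle", {
  mask <- discMask(128, 30)
  geom <- geomForMask(mask)
  i <- matrix(1, 128, 128)
  band <- extractSurfaceBand(geom, i, i, runConfig())
  bp <- bandPixels(band)
  mp <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  d2 <- apply(bg, 1, function(p) min((p[1] - mp[, 1])^2 +
                                       (p[2] - mp[, 2])^2))
  truth <- bg[d2 >= 100 & d2 <= 625, , drop = FALSE]
  expect_setequal(paste(bp$x, bp$y), paste(truth[, 2], truth[, 1]))
})

test_that("band geometry is a pure function of the mask", {
  pipe <- midPipeline()
  other <- extractSurfaceBand(pipe$geom, pipe$fr$I488 * 0 + 7,
                              pipe$fr$I405 * 0 + 3, pipe$cfg)
  a <- bandPixels(pipe$band); b <- bandPixels(other)
  expect_identical(a[c("x", "y", "distPx", "sUm", "side")],
                   b[c("x", "y", "distPx", "sUm", "side")])
})

test_that("longitudinal coordinates are equivariant under 90-degree rotation", {
  pipe <- midPipeline()
  cfg <- pipe$cfg
  rot <- function(m) t(m)[, nrow(m):1] # 90 degrees clockwise
  g2 <- rootGeometry(rot(pipe$fr$I488), rot(pipe$fr$I405), cfg,
                     pixelSize(pipe$ph$stack), gravity = c(-1, 0))
  b2 <- extractSurfaceBand(g2, rot(pipe$fr$I488), rot(pipe$fr$I405), cfg)
  p1 <- profileBins(binProfile(pipe$band, cfg))
  p2 <- profileBins(binProfile(b2, cfg))
  m <- merge(p1[p1$side == "both" & p1$valid, c("positionUm", "meanRatio")],
             p2[p2$side == "both" & p2$valid, c("positionUm", "meanRatio")],
             by = "positionUm")
  expect_gt(nrow(m), 10)
  expect_equal(m$meanRatio.x, m$meanRatio.y, tolerance = 1e-3)
})

test_that("left and right flanks are balanced on a straight phantom", {
  pipe <- midPipeline()
  p <- bandPixels(pipe$band)
  p <- p[p$sUm > 50 & p$sUm < 250, ] # away from tip cap and border
  nl <- sum(p$side == "left"); nr <- sum(p$side == "right")
  expect_lt(abs(nl - nr) / max(nl, nr), 0.1)
})
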
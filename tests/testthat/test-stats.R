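test_that("identical samples give relative effect 0.5 and p near 1", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8)
  r <- rankTestTwoSample(x, x)
  expect_equal(r$effect, 0.5)
  expect_gt(r$p.value, 0.99)
  ## all values tied across both samples: degenerate by convention
  r2 <- rankTestTwoSample(rep(2, 6), rep(2, 7))
  expect_equal(r2$effect, 0.5)
  expect_equal(r2$p.value, 1)
  expect_error(rankTestTwoSample(1:3, 1:10), class = "rhizopH_precondition")
})

test_that("the relative effect equals exhaustive enumeration for all small samples", {
  set.seed(31)
  for (i in 1:300) {
    x <- sample(1:6, sample(5:8, 1), replace = TRUE)
    y <- sample(1:6, sample(5:8, 1), replace = TRUE)
    bf <- mean(outer(x, y, "<")) + 0.5 * mean(outer(x, y, "=="))
    expect_equal(rankTestTwoSample(x, y)$effect, bf, tolerance = 1e-12)
  }
  ## spec worked example
  r <- rankTestTwoSample(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  bf <- mean(outer(1:5, 2:6, "<")) + 0.5 * mean(outer(1:5, 2:6, "=="))
  expect_equal(r$effect, bf)
})

test_that("the test is invariant under joint monotone transforms", {
  set.seed(32)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  r1 <- rankTestTwoSample(x, y)
  r2 <- rankTestTwoSample(exp(x), exp(y))
  expect_equal(r1$effect, r2$effect)
  expect_equal(r1$p.value, r2$p.value)
})

test_that("type-I error is near nominal under the null", {
  ## the full 10,000-simulation calibration runs in the acceptance
  ## suite; this sanity check uses 2,000
  set.seed(33)
  rej <- 0L
  for (i in 1:2000) {
    if (rankTestTwoSample(rnorm(20), rnorm(20))$p.value < 0.05)
      rej <- rej + 1L
  }
  expect_gt(rej / 2000, 0.03)
  expect_lt(rej / 2000, 0.07)
})

test_that("alkalinization factors are 1 for self-comparison and scale-invariant", {
  grid <- seq(6.5, 600, by = 13)
  g1 <- syntheticGroup(6, grid, delta = 0, seed = 40)
  g2 <- syntheticGroup(6, grid, delta = 0, seed = 50)
  af <- alkalinizationFactor(g2, g1, nBoot = 200, seed = 1)
  expect_true(all(abs(af$AF - 1) < 0.05))
  expect_true(all(af$lo <= af$AF & af$AF <= af$hi))
  ## multiplying every profile by a constant leaves AF unchanged
  scaleProf <- function(p, k) {
    b <- profileBins(p); b$pH <- b$pH * k
    new("PHProfile", bins = b, binUm = p@binUm, pixelSize = p@pixelSize,
        calibrated = TRUE)
  }
  af2 <- alkalinizationFactor(lapply(g2, scaleProf, k = 3),
                              lapply(g1, scaleProf, k = 3),
                              nBoot = 200, seed = 1)
  expect_equal(af2$AF, af$AF, tolerance = 1e-12)
  ## programmed window shows AF > 1 exactly there
  g3 <- syntheticGroup(6, grid, delta = 0.3, windowUm = c(200, 500),
                       seed = 60)
  af3 <- alkalinizationFactor(g3, g1, nBoot = 200, seed = 1)
  inWin <- af3$positionUm >= 213 & af3$positionUm <= 487
  outWin <- af3$positionUm < 187 | af3$positionUm > 513
  expect_true(all(af3$AF[inWin] > 1.02))
  expect_true(all(abs(af3$AF[outWin] - 1) < 0.02))
  ## disjoint ranges cannot be aligned
  gLow <- syntheticGroup(3, seq(6.5, 100, by = 13), seed = 70)
  gHigh <- syntheticGroup(3, seq(306.5, 400, by = 13), seed = 80)
  expect_error(alkalinizationFactor(gLow, gHigh, nBoot = 10),
               class = "rhizopH_alignment")
  expect_error(alkalinizationFactor(g1[1:2], g2, nBoot = 10),
               class = "rhizopH_precondition")
})

test_that("alkaline domains are detected with analytic descriptors", {
  set.seed(9)
  pos <- seq(6.5, 700, by = 13)
  v <- 5.2 + 0.5 * exp(-(pos - 350)^2 / (2 * 60^2)) +
    rnorm(length(pos), 0, 0.005)
  d <- detectAlkalineDomain(syntheticProfile(pos, v), c(150, 550))
  expect_true(d$present)
  expect_lte(abs(d$peakPositionUm - 350), 13)
  expect_lt(abs(d$amplitude - 0.5) / 0.5, 0.10)
  expect_lt(abs(d$fwhmUm - 2.355 * 60) / (2.355 * 60), 0.15)
  expect_false(d$boundaryLimited)
  ## flat + noise: absent, and absence is explicit (NA, not zeros)
  set.seed(11)
  flat <- detectAlkalineDomain(
    syntheticProfile(pos, 5.2 + rnorm(length(pos), 0, 0.01)), c(150, 550))
  expect_false(flat$present)
  expect_true(is.na(flat$amplitude))
  ## bump truncated by the window edge: flagged boundary-limited
  vTr <- 5.2 + 0.5 * exp(-(pos - 520)^2 / (2 * 60^2))
  dTr <- detectAlkalineDomain(syntheticProfile(pos, vTr), c(150, 550))
  expect_true(dTr$present)
  expect_true(dTr$boundaryLimited)
  expect_error(detectAlkalineDomain(syntheticProfile(pos, v), c(900, 1000)),
               class = "rhizopH_window")
})

test_that("profile comparison flags the programmed window and respects preconditions", {
  grid <- seq(6.5, 600, by = 13)
  ctrl <- syntheticGroup(8, grid, delta = 0, seed = 100)
  trt <- syntheticGroup(8, grid, delta = 0.3, windowUm = c(200, 500),
                        seed = 200)
  cmp <- compareProfiles(trt, ctrl, alpha = 0.05, adjust = "holm")
  inWin <- cmp$positionUm >= 213 & cmp$positionUm <= 487
  outWin <- cmp$positionUm < 187 | cmp$positionUm > 513
  expect_true(all(cmp$significant[inWin]))
  expect_lt(mean(cmp$significant[outWin]), 0.05)
  expect_identical(attr(cmp, "adjust"), "holm")
  expect_error(compareProfiles(trt[1:2], ctrl),
               class = "rhizopH_precondition")
})

test_that("many-to-one comparison flags only the deviant group", {
  grid <- seq(6.5, 600, by = 13)
  groups <- list(
    control = syntheticGroup(8, grid, delta = 0, seed = 300),
    same1 = syntheticGroup(8, grid, delta = 0, seed = 400),
    deviant = syntheticGroup(8, grid, delta = 0.3,
                             windowUm = c(200, 500), seed = 500))
  res <- manyToOneComparison(groups, "control", alpha = 0.01)
  inWin <- res$deviant$positionUm >= 213 & res$deviant$positionUm <= 487
  expect_true(all(res$deviant$significant[inWin]))
  expect_lt(mean(res$same1$significant, na.rm = TRUE), 0.05)
  expect_error(manyToOneComparison(groups, "missing"),
               class = "rhizopH_control")
})

test_that("penetration efficiency reproduces hand-checked arithmetic", {
  toy <- data.frame(
    genotype = rep(c("Col-0", "mutant"), 2),
    pore_size_um = 139,
    n_penetrated = c(8, 4, 5, 4),
    n_total = 10,
    replicate = c(1, 1, 2, 2))
  eff <- penetrationEfficiency(toy)
  mut <- eff[eff$genotype == "mutant", ]
  per <- attr(eff, "perReplicate")
  expect_equal(sort(per$norm[per$genotype == "mutant"]), c(0.5, 0.8))
  expect_equal(mut$meanEfficiency, 0.65)
  ## the reference variant normalizes to mean 1.0
  ref <- eff[eff$genotype == "Col-0", ]
  expect_equal(ref$meanEfficiency, 1.0)
  ## equal raw efficiencies across repeats: every reference value is 1
  toy2 <- toy; toy2$n_penetrated <- c(8, 4, 8, 4)
  per2 <- attr(penetrationEfficiency(toy2), "perReplicate")
  expect_true(all(per2$norm[per2$genotype == "Col-0"] == 1))
  ## zero-penetration variant stays 0 in every replicate
  toy3 <- toy; toy3$n_penetrated[c(2, 4)] <- 0
  eff3 <- penetrationEfficiency(toy3)
  expect_equal(eff3$meanEfficiency[eff3$genotype == "mutant"], 0)
  ## count-scale invariance
  toy4 <- toy
  toy4$n_penetrated <- toy$n_penetrated * 3
  toy4$n_total <- toy$n_total * 3
  expect_equal(penetrationEfficiency(toy4)$meanEfficiency,
               eff$meanEfficiency)
  ## zero reference efficiency drops that replicate with a warning
  toy5 <- toy; toy5$n_penetrated[3] <- 0
  expect_warning(eff5 <- penetrationEfficiency(toy5), "zero reference")
  expect_equal(eff5$nReplicates[eff5$genotype == "mutant"], 1L)
})
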
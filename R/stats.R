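## Derived metrics (alkalinization factor, alkaline-domain descriptors,
## penetration efficiency) and the rank-based per-position comparison
## used for profile figures. The two-sample test is the Brunner-Munzel
## rank test for the relative effect P(X < Y) + 0.5 P(X = Y), which
## tolerates ties and unequal variances.

#' Brunner-Munzel two-sample rank test
#'
#' Estimates the relative effect p = P(X < Y) + 0.5 P(X = Y) via
#' midranks and tests p = 0.5 with the Brunner-Munzel statistic and a
#' Satterthwaite-type t approximation. With zero rank variance
#' (complete separation) the two-sided p-value falls back to the
#' permutation lower bound 2 / choose(nx + ny, nx); with all values tied
#' the result is degenerate (effect 0.5, p 1).
#'
#' @param x,y numeric samples, each of length >= 5.
#' @return list(effect, statistic, df, p.value, nx, ny).
#' @export
rankTestTwoSample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 5 || n2 < 5)
    rzStop("each sample needs at least 5 values", "precondition")
  r <- rank(c(x, y)) # midranks
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  effect <- (m2 - (n2 + 1) / 2) / n1
  ri1 <- rank(x); ri2 <- rank(y)
  v1 <- sum((r1 - ri1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ri2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  sig <- n1 * v1 + n2 * v2
  if (sig <= 0) {
    if (abs(effect - 0.5) < 1e-12)
      return(list(effect = 0.5, statistic = 0, df = NA_real_, p.value = 1,
                  nx = n1, ny = n2))
    p <- min(1, 2 / choose(n1 + n2, n1))
    return(list(effect = effect, statistic = sign(effect - 0.5) * Inf,
                df = NA_real_, p.value = p, nx = n1, ny = n2))
  }
  stat <- (n1 * n2 * (m2 - m1)) / ((n1 + n2) * sqrt(sig))
  df <- sig^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(effect = effect, statistic = stat, df = df, p.value = p,
       nx = n1, ny = n2)
}

## Per-root values at each common bin position; profiles must share the
## binning grid (same config) or be linearly resampled.
profileMatrixOnGrid <- function(profiles, grid, side = "both") {
  vapply(profiles, profileValuesOnGrid, numeric(length(grid)),
         grid = grid, side = side)
}

## Common position grid across two groups of profiles: positions where
## at least minPer profiles per group have a valid bin.
commonGrid <- function(groupA, groupB, side = "both", minPer = NULL) {
  posOf <- function(p) {
    b <- profileBins(p)
    b$positionUm[b$side == side & b$valid]
  }
  allA <- unlist(lapply(groupA, posOf))
  allB <- unlist(lapply(groupB, posOf))
  if (is.null(minPer)) minPer <- c(length(groupA), length(groupB))
  ta <- table(allA); tb <- table(allB)
  pa <- as.numeric(names(ta))[ta >= minPer[1]]
  pb <- as.numeric(names(tb))[tb >= minPer[2]]
  grid <- sort(intersect(pa, pb))
  if (!length(grid))
    rzStop("no positional overlap between the groups", "alignment")
  grid
}

#' Alkalinization factor curve
#'
#' Per-position ratio of the treated group's mean profile to the control
#' group's mean profile, with a bootstrap confidence band (resampling
#' roots within each group).
#'
#' @param treated,control lists of \code{PHProfile} (>= 3 each).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param side profile side to use.
#' @return data.frame (positionUm, AF, lo, hi) with the factor
#'   definition recorded in attribute \code{"definition"}.
#' @export
alkalinizationFactor <- function(treated, control, nBoot = 1000, seed = 1L,
                                 conf = 0.95, side = "both") {
  if (length(treated) < 3 || length(control) < 3)
    rzStop("need at least 3 profiles per group", "precondition")
  grid <- commonGrid(treated, control, side,
                     minPer = c(min(3, length(treated)),
                                min(3, length(control))))
  mt <- profileMatrixOnGrid(treated, grid, side)
  mc <- profileMatrixOnGrid(control, grid, side)
  af <- rowMeans(mt, na.rm = TRUE) / rowMeans(mc, na.rm = TRUE)
  qs <- withSeed(seed, {
    boots <- vapply(seq_len(nBoot), function(b) {
      it <- sample.int(ncol(mt), replace = TRUE)
      ic <- sample.int(ncol(mc), replace = TRUE)
      rowMeans(mt[, it, drop = FALSE], na.rm = TRUE) /
        rowMeans(mc[, ic, drop = FALSE], na.rm = TRUE)
    }, numeric(length(grid)))
    a <- (1 - conf) / 2
    apply(boots, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  })
  out <- data.frame(positionUm = grid, AF = af, lo = qs[1, ], hi = qs[2, ])
  attr(out, "definition") <- "ratio of group mean profiles per position"
  rownames(out) <- NULL
  out
}

#' Detect and describe the alkaline domain of a profile
#'
#' The baseline is the line through the profile minima flanking the peak
#' inside the search window; the domain is reported when the
#' baseline-subtracted peak amplitude exceeds \code{k} times the robust
#' noise SD of the differenced profile. The FWHM is measured on the
#' baseline-subtracted bump by linear interpolation of the half-maximum
#' crossings.
#'
#' @param profile a \code{PHProfile}.
#' @param windowUm search window, c(lo, hi) um from the tip.
#' @param k detection threshold in noise SDs (default 3).
#' @param side profile side.
#' @return list(present, peakPositionUm, amplitude, fwhmUm,
#'   boundaryLimited, baseline, noiseSD). Amplitude is in ratio units,
#'   or in pH if the profile is calibrated. When no domain is detected,
#'   \code{present} is FALSE and the descriptors are NA (never zeros).
#' @export
detectAlkalineDomain <- function(profile, windowUm = c(150, 550), k = 3,
                                 side = "both") {
  b <- profileBins(profile)
  b <- b[b$side == side & b$valid, , drop = FALSE]
  col <- if (profile@calibrated) "pH" else "meanRatio"
  inWin <- b$positionUm >= windowUm[1] & b$positionUm <= windowUm[2]
  if (sum(inWin) < 10)
    rzStop("fewer than 10 valid bins in the search window", "window")
  s <- b$positionUm[inWin]
  v <- b[[col]][inWin]
  noiseSD <- stats::mad(diff(v)) / sqrt(2)
  ## detection runs on a lightly smoothed profile so single noisy bins
  ## cannot mimic a domain; descriptors are then read from the raw bins
  nv <- length(v)
  half <- 2L
  cs <- cumsum(c(0, v))
  loI <- pmax(seq_len(nv) - half, 1L); hiI <- pmin(seq_len(nv) + half, nv)
  vS <- (cs[hiI + 1] - cs[loI]) / (hiI - loI + 1)
  ipS <- which.max(vS)
  leftIdx <- if (ipS > 1) which.min(vS[1:ipS]) else 1L
  rightIdx <- if (ipS < nv) ipS - 1L + which.min(vS[ipS:nv]) else nv
  absent <- list(present = FALSE, peakPositionUm = NA_real_,
                 amplitude = NA_real_, fwhmUm = NA_real_,
                 boundaryLimited = NA, baseline = NULL, noiseSD = noiseSD)
  if (leftIdx == ipS || rightIdx == ipS) {
    ## peak at a window edge: the bump is truncated; report it with a
    ## one-sided baseline when it still clears the threshold
    minIdx <- if (leftIdx == ipS) rightIdx else leftIdx
    if (minIdx == ipS ||
        vS[ipS] - vS[minIdx] <= k * max(noiseSD, 1e-12)) return(absent)
    nb <- max(1L, ipS - 2L):min(nv, ipS + 2L)
    ip <- nb[which.max(v[nb])]
    return(list(present = TRUE, peakPositionUm = s[ip],
                amplitude = v[ip] - v[minIdx], fwhmUm = NA_real_,
                boundaryLimited = TRUE,
                baseline = list(sUm = s[minIdx], value = v[minIdx]),
                noiseSD = noiseSD))
  }
  blS <- vS[leftIdx] + (vS[rightIdx] - vS[leftIdx]) *
    (s[ipS] - s[leftIdx]) / (s[rightIdx] - s[leftIdx])
  if (!is.finite(vS[ipS] - blS) ||
      vS[ipS] - blS <= k * max(noiseSD, 1e-12)) return(absent)
  ## raw-profile descriptors: peak near the smoothed peak, baseline line
  ## through the raw values at the flanking-minimum positions
  nb <- max(leftIdx + 1L, ipS - 2L):min(rightIdx - 1L, ipS + 2L)
  ip <- nb[which.max(v[nb])]
  bl <- function(x) {
    v[leftIdx] + (v[rightIdx] - v[leftIdx]) *
      (x - s[leftIdx]) / (s[rightIdx] - s[leftIdx])
  }
  bump <- v - bl(s)
  amp <- bump[ip]
  half <- amp / 2
  seg <- leftIdx:rightIdx
  crossAt <- function(iA, iB) {
    ## linear interpolation of the half-max crossing between bins
    s[iA] + (half - bump[iA]) * (s[iB] - s[iA]) / (bump[iB] - bump[iA])
  }
  lo <- NA_real_; hi <- NA_real_
  for (i in seq(ip, leftIdx + 1L, by = -1L)) {
    if (bump[i - 1] <= half && bump[i] >= half) { lo <- crossAt(i - 1, i); break }
  }
  for (i in seq(ip, rightIdx - 1L, by = 1L)) {
    if (bump[i + 1] <= half && bump[i] >= half) { hi <- crossAt(i + 1, i); break }
  }
  boundaryLimited <- is.na(lo) || is.na(hi)
  fwhm <- if (is.na(lo) || is.na(hi)) NA_real_ else hi - lo
  list(present = TRUE, peakPositionUm = s[ip], amplitude = amp,
       fwhmUm = fwhm, boundaryLimited = boundaryLimited,
       baseline = list(sUm = s[c(leftIdx, rightIdx)],
                       value = v[c(leftIdx, rightIdx)]),
       noiseSD = noiseSD)
}

#' Per-position rank comparison of two profile groups
#'
#' At each common bin position the per-root bin values of group A and
#' group B are compared with [rankTestTwoSample()]. By default each
#' position is flagged at \code{alpha} without multiplicity adjustment,
#' mirroring per-position significance bars; Holm adjustment across
#' positions is available and the setting is recorded in the output.
#'
#' @param groupA,groupB lists of \code{PHProfile} (>= 5 each).
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "holm" across positions.
#' @param side profile side.
#' @return data.frame (positionUm, effect, statistic, p, pAdj,
#'   significant) with attributes alpha, adjust and group sizes.
#' @export
compareProfiles <- function(groupA, groupB, alpha = 0.05,
                            adjust = c("none", "holm"), side = "both") {
  adjust <- match.arg(adjust)
  if (length(groupA) < 5 || length(groupB) < 5)
    rzStop("need at least 5 profiles per group", "precondition")
  grid <- commonGrid(groupA, groupB, side,
                     minPer = c(5, 5))
  ma <- profileMatrixOnGrid(groupA, grid, side)
  mb <- profileMatrixOnGrid(groupB, grid, side)
  res <- lapply(seq_along(grid), function(i) {
    a <- ma[i, ]; bv <- mb[i, ]
    if (sum(!is.na(a)) < 5 || sum(!is.na(bv)) < 5)
      return(data.frame(positionUm = grid[i], effect = NA_real_,
                        statistic = NA_real_, p = NA_real_))
    t <- rankTestTwoSample(a[!is.na(a)], bv[!is.na(bv)])
    data.frame(positionUm = grid[i], effect = t$effect,
               statistic = t$statistic, p = t$p.value)
  })
  out <- do.call(rbind, res)
  out$pAdj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  attr(out, "n") <- c(A = length(groupA), B = length(groupB))
  out
}

#' Many-to-one profile comparison against a control group
#'
#' Each non-control group is compared to the control with
#' [compareProfiles()]; Holm adjustment is then applied across groups at
#' each position (many-to-one family).
#'
#' @param groups named list of profile lists.
#' @param controlName name of the control group in \code{groups}.
#' @param alpha significance level.
#' @param side profile side.
#' @return named list of comparison data.frames (one per non-control
#'   group) with across-group Holm-adjusted \code{pAdj}.
#' @export
manyToOneComparison <- function(groups, controlName, alpha = 0.05,
                                side = "both") {
  if (!controlName %in% names(groups))
    rzStop(paste0("control group '", controlName, "' not found"), "control")
  others <- setdiff(names(groups), controlName)
  if (length(others) < 1)
    rzStop("need at least one non-control group", "precondition")
  ctrl <- groups[[controlName]]
  cmps <- lapply(others, function(nm)
    compareProfiles(groups[[nm]], ctrl, alpha = alpha, adjust = "none",
                    side = side))
  names(cmps) <- others
  ## Holm across groups at each shared position
  allPos <- sort(unique(unlist(lapply(cmps, function(d) d$positionUm))))
  for (pos in allPos) {
    ps <- vapply(cmps, function(d) {
      i <- match(pos, d$positionUm)
      if (is.na(i)) NA_real_ else d$p[i]
    }, numeric(1))
    ok <- !is.na(ps)
    if (!any(ok)) next
    adj <- stats::p.adjust(ps[ok], "holm")
    j <- 1
    for (g in names(cmps)[ok]) {
      i <- match(pos, cmps[[g]]$positionUm)
      cmps[[g]]$pAdj[i] <- adj[j]
      cmps[[g]]$significant[i] <- adj[j] < alpha
      j <- j + 1
    }
  }
  for (g in names(cmps)) attr(cmps[[g]], "adjust") <- "holm-across-groups"
  cmps
}

#' Mesh penetration efficiency, normalized per replicate
#'
#' Within each replicate every variant's raw efficiency
#' (n_penetrated / n_total) is divided by the reference variant's raw
#' efficiency in that replicate; the reference variant itself is instead
#' normalized to its across-replicate mean raw efficiency. Replicates in
#' which the reference did not penetrate at all are excluded with a
#' warning.
#'
#' @param table data.frame as from [loadPenetrationTable()].
#' @param reference list(genotype, pore_size_um) naming the reference
#'   variant.
#' @return data.frame (genotype, pore_size_um, meanEfficiency,
#'   sdEfficiency, nReplicates); per-replicate values in attribute
#'   \code{"perReplicate"}.
#' @export
penetrationEfficiency <- function(table,
                                  reference = list(genotype = "Col-0",
                                                   pore_size_um = 139)) {
  isRef <- table$genotype == reference$genotype &
    table$pore_size_um == reference$pore_size_um
  reps <- sort(unique(table$replicate))
  refRows <- table[isRef, , drop = FALSE]
  if (!all(reps %in% refRows$replicate))
    rzStop("reference variant missing from some replicates", "precondition")
  refEff <- refRows$n_penetrated / refRows$n_total
  names(refEff) <- as.character(refRows$replicate)
  zero <- refEff == 0
  if (any(zero)) {
    rzWarn(sprintf("excluding %d replicate(s) with zero reference efficiency",
                   sum(zero)))
    keep <- names(refEff)[!zero]
    table <- table[as.character(table$replicate) %in% keep, , drop = FALSE]
    refEff <- refEff[!zero]
  }
  refMean <- mean(refEff)
  table$eff <- table$n_penetrated / table$n_total
  isRef <- table$genotype == reference$genotype &
    table$pore_size_um == reference$pore_size_um
  table$norm <- ifelse(isRef, table$eff / refMean,
                       table$eff / refEff[as.character(table$replicate)])
  agg <- stats::aggregate(
    list(meanEfficiency = table$norm),
    by = list(genotype = table$genotype, pore_size_um = table$pore_size_um),
    FUN = mean)
  sds <- stats::aggregate(
    list(sdEfficiency = table$norm),
    by = list(genotype = table$genotype, pore_size_um = table$pore_size_um),
    FUN = function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  ns <- stats::aggregate(
    list(nReplicates = table$norm),
    by = list(genotype = table$genotype, pore_size_um = table$pore_size_um),
    FUN = length)
  out <- merge(merge(agg, sds), ns)
  out <- out[order(out$genotype, out$pore_size_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "perReplicate") <- table[, c("genotype", "pore_size_um",
                                         "replicate", "eff", "norm")]
  out
}
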
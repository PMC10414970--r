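## Per-frame spatial scaffold: the root is the dark (dye-excluded) object
## in bright stained medium. Segmentation thresholds the summed channels
## (the ratio is undefined at low counts), the midline is a pruned
## skeleton, and the surface band is cut from the exact Euclidean
## distance transform of the medium.

## Neighbor view: out[y, x] = m[y + dy, x + dx], zero-padded.
nbShift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

## Zhang-Suen thinning on a binary matrix (1 = object), vectorized.
zhangSuenThin <- function(m) {
  m <- m * 1L
  offs <- list(P2 = c(-1, 0), P3 = c(-1, 1), P4 = c(0, 1), P5 = c(1, 1),
               P6 = c(1, 0), P7 = c(1, -1), P8 = c(0, -1), P9 = c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) nbShift(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      seqP <- P[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqP[[i]] == 0L) * (seqP[[i + 1]] == 1L)
      if (step == 1) {
        cond <- (P$P2 * P$P4 * P$P6 == 0L) & (P$P4 * P$P6 * P$P8 == 0L)
      } else {
        cond <- (P$P2 * P$P4 * P$P8 == 0L) & (P$P2 * P$P6 * P$P8 == 0L)
      }
      del <- (m == 1L) & (B >= 2L) & (B <= 6L) & (A == 1L) & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Segment the dark root from bright stained medium
#'
#' The dye stains the medium and the root surface but not the root
#' tissue, so the root is the dark object. The summed channels are
#' Otsu-thresholded, the largest dark component is kept, closed
#' morphologically, and holes are filled.
#'
#' @param i488,i405 intensity matrices of one frame.
#' @param config a \code{RunConfig} (threshold method, closing radius,
#'   minimum area).
#' @return logical mask, TRUE on the root.
#' @export
segmentRoot <- function(i488, i405, config = runConfig()) {
  S <- i488 + i405
  rng <- range(S)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1))
    rzStop("image is uniform; no dark root object found", "NoRootFound")
  norm <- (S - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  dark <- norm < thr
  if (mean(dark) > 0.8)
    rzStop("dark fraction exceeds 80% of the image: staining failure?",
           "staining_failure")
  lab <- EBImage::bwlabel(dark * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config@minAreaPx)
  if (!length(keep))
    rzStop("no dark component above the minimum area: no root found",
           "NoRootFound")
  big <- keep[which.max(sizes[keep])]
  m <- (lab == big) * 1
  br <- 2 * round(config@closeRadiusPx) + 1
  if (br >= 3)
    m <- EBImage::closing(m, EBImage::makeBrush(br, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab2 <- EBImage::bwlabel(m)
  sizes2 <- tabulate(lab2[lab2 > 0])
  m <- lab2 == which.max(sizes2)
  matrix(as.logical(m), nrow(S), ncol(S))
}

## Ordered pixel chain of the skeleton's longest geodesic, as an
## m x 2 (x, y) matrix. Taking the longest endpoint-to-endpoint geodesic
## drops spur branches.
skeletonLongestPath <- function(skel) {
  pts <- which(skel == 1L, arr.ind = TRUE) # (row=y, col=x)
  if (nrow(pts) < 2)
    rzStop("degenerate skeleton (fewer than 2 pixels): cannot form a midline",
           "degenerate_topology")
  ny <- nrow(skel)
  id <- matrix(NA_integer_, nrow(skel), ncol(skel))
  id[pts] <- seq_len(nrow(pts))
  edges <- NULL
  w <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    sh <- nbShift(skel, o[1], o[2])
    both <- which(skel == 1L & sh == 1L, arr.ind = TRUE)
    if (nrow(both)) {
      a <- id[both]
      b <- id[cbind(both[, 1] + o[1], both[, 2] + o[2])]
      edges <- rbind(edges, cbind(a, b))
      w <- c(w, rep(sqrt(sum(o^2)), nrow(both)))
    }
  }
  if (is.null(edges))
    rzStop("skeleton pixels are disconnected", "degenerate_topology")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vMain <- which(comp$membership == main)
  deg <- igraph::degree(g, v = vMain)
  ends <- vMain[deg == 1]
  if (length(ends) < 2)
    rzStop("skeleton has no endpoint pair (loop): degenerate topology",
           "degenerate_topology")
  dm <- igraph::distances(g, v = ends, to = ends)
  ij <- which(dm == max(dm[is.finite(dm)]), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(g, from = ends[ij[1]], to = ends[ij[2]],
                               output = "vpath")$vpath[[1]]
  v <- as.integer(sp)
  cbind(x = pts[v, 2], y = pts[v, 1])
}

## Moving-average smoothing of a polyline, window shrinking at the ends.
smoothPolyline <- function(pts, k = 7L) {
  n <- nrow(pts)
  if (n < 3 || k < 3) return(pts)
  half <- k %/% 2
  sm <- function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  cbind(x = sm(pts[, 1]), y = sm(pts[, 2]))
}

#' Extract the root midline from a mask
#'
#' Zhang-Suen thinning pruned to its longest endpoint-to-endpoint
#' geodesic, smoothed, and extended at both ends by the interior
#' distance-transform value along the local direction so the midline
#' reaches the mask boundary (the thinning retreats about one local
#' radius from each end). The cumulative arc length in microns is
#' attached as attribute \code{"arcLengthUm"} (measured from the first
#' point; orientation is fixed later by [detectTip()]).
#'
#' @param mask logical root mask.
#' @param pixelSize microns per pixel.
#' @return m x 2 matrix of (x, y) midline coordinates.
#' @export
extractMidline <- function(mask, pixelSize = 1) {
  bb <- which(mask, arr.ind = TRUE)
  if (!nrow(bb)) rzStop("empty mask", "NoRootFound")
  y0 <- max(1, min(bb[, 1]) - 1L); y1 <- min(nrow(mask), max(bb[, 1]) + 1L)
  x0 <- max(1, min(bb[, 2]) - 1L); x1 <- min(ncol(mask), max(bb[, 2]) + 1L)
  sub <- mask[y0:y1, x0:x1]
  skel <- zhangSuenThin(sub)
  path <- skeletonLongestPath(skel)
  path[, 1] <- path[, 1] + (x0 - 1L)
  path[, 2] <- path[, 2] + (y0 - 1L)
  path <- smoothPolyline(path, 7L)
  ## extend both ends to the mask boundary using the interior EDT
  din <- EBImage::distmap(mask * 1)
  n <- nrow(path)
  extend <- function(pEnd, pIn) {
    d <- pEnd - pIn
    nd <- sqrt(sum(d^2))
    if (nd == 0) return(NULL)
    d <- d / nd
    r <- din[round(pEnd[2]), round(pEnd[1])]
    if (r <= 0.5) return(NULL)
    p <- pEnd + d * r
    p[1] <- max(1, min(ncol(mask), p[1]))
    p[2] <- max(1, min(nrow(mask), p[2]))
    p
  }
  k <- min(6L, n - 1L)
  headPt <- extend(path[1, ], path[1 + k, ])
  tailPt <- extend(path[n, ], path[n - k, ])
  if (!is.null(headPt)) path <- rbind(headPt, path)
  if (!is.null(tailPt)) path <- rbind(path, tailPt)
  steps <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  attr(path, "arcLengthUm") <- c(0, cumsum(steps)) * pixelSize
  colnames(path) <- c("x", "y")
  path
}

#' Locate the root tip and tip tangent
#'
#' The tip is the midline endpoint that does not sit on the image border
#' (the root enters the field shootward); if both or neither endpoint
#' touches a border, the endpoint with the largest projection on the
#' gravity vector (deepest) is taken. The tangent is the principal
#' direction of the midline points nearest the tip (up to 60 points,
#' about 40 um at typical sampling), oriented tipward; the span averages
#' out the staircase bias a thinned skeleton carries at shallow angles
#' to the pixel grid.
#'
#' @param midlinePts m x 2 (x, y) midline matrix (either orientation).
#' @param mask logical root mask (supplies the image dimensions).
#' @param gravity unit gravity vector in image coordinates.
#' @return list with \code{tipEnd} (1 or 2, meaning first/last midline
#'   point), \code{tip} (x, y) and \code{tangent} (unit, tipward).
#' @export
detectTip <- function(midlinePts, mask, gravity = c(0, 1)) {
  n <- nrow(midlinePts)
  if (n < 25) rzStop("midline shorter than 25 points: root too short",
                     "short_root")
  ny <- nrow(mask); nx <- ncol(mask)
  ends <- rbind(midlinePts[1, ], midlinePts[n, ])
  onBorder <- apply(ends, 1, function(p)
    p[1] <= 2 || p[1] >= nx - 1 || p[2] <= 2 || p[2] >= ny - 1)
  if (sum(onBorder) == 1) {
    tipEnd <- which(!onBorder)
  } else {
    proj <- ends %*% unitVec(gravity)
    tipEnd <- which.max(proj)
  }
  nFit <- min(60L, n)
  idx <- if (tipEnd == 1) 1:nFit else n:(n - nFit + 1L)
  pts <- midlinePts[idx, , drop = FALSE]
  pc <- stats::prcomp(pts, center = TRUE)
  dir <- pc$rotation[, 1]
  outward <- pts[1, ] - pts[nFit, ] # from interior point toward the tip
  if (sum(dir * outward) < 0) dir <- -dir
  list(tipEnd = tipEnd, tip = as.numeric(ends[tipEnd, ]),
       tangent = as.numeric(unitVec(dir)))
}

#' Full per-frame geometry: mask, contour, oriented midline, tip
#'
#' @param i488,i405 one frame's channel matrices.
#' @param config a \code{RunConfig}.
#' @param pixelSize microns per pixel.
#' @param gravity unit gravity vector.
#' @return a \code{RootGeometry}.
#' @export
rootGeometry <- function(i488, i405, config = runConfig(), pixelSize = 1,
                         gravity = c(0, 1)) {
  mask <- segmentRoot(i488, i405, config)
  ml <- extractMidline(mask, pixelSize)
  dt <- detectTip(ml, mask, gravity)
  if (dt$tipEnd == 2) ml <- ml[rev(seq_len(nrow(ml))), , drop = FALSE]
  steps <- sqrt(diff(ml[, 1])^2 + diff(ml[, 2])^2)
  arc <- c(0, cumsum(steps)) * pixelSize
  ## contour: mask pixels with a 4-neighbor outside the mask
  m1 <- mask * 1L
  inner <- nbShift(m1, 1, 0) & nbShift(m1, -1, 0) &
    nbShift(m1, 0, 1) & nbShift(m1, 0, -1)
  cpts <- which(mask & !inner, arr.ind = TRUE)
  contour <- cbind(x = cpts[, 2], y = cpts[, 1])
  new("RootGeometry", mask = mask, contour = contour,
      midline = ml, arcLengthUm = as.numeric(arc),
      tip = as.numeric(ml[1, ]), tipTangent = dt$tangent,
      pixelSize = pixelSize)
}

## Nearest midline point for pixel coordinates, coarse-to-fine.
## Returns integer midline indices. Exact to within the coarse stride
## (s error of a few px at most on smooth midlines).
nearestMidlineIndex <- function(px, py, ml, stride = 4L, chunk = 4000L) {
  n <- nrow(ml)
  ci <- seq(1L, n, by = stride)
  if (ci[length(ci)] != n) ci <- c(ci, n)
  out <- integer(length(px))
  for (start in seq(1L, length(px), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(px))
    dx <- outer(px[sel], ml[ci, 1], "-")
    dy <- outer(py[sel], ml[ci, 2], "-")
    coarse <- ci[max.col(-(dx * dx + dy * dy), ties.method = "first")]
    best <- coarse
    bestD <- (px[sel] - ml[coarse, 1])^2 + (py[sel] - ml[coarse, 2])^2
    for (off in setdiff(-(stride):stride, 0L)) {
      j <- pmin(pmax(coarse + off, 1L), n)
      d <- (px[sel] - ml[j, 1])^2 + (py[sel] - ml[j, 2])^2
      better <- d < bestD
      best[better] <- j[better]
      bestD[better] <- d[better]
    }
    out[sel] <- best
  }
  out
}

## Shootward unit tangents along the midline (tip first).
midlineTangents <- function(ml) {
  n <- nrow(ml)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  tx <- ml[ip, 1] - ml[im, 1]
  ty <- ml[ip, 2] - ml[im, 2]
  nn <- sqrt(tx^2 + ty^2)
  nn[nn == 0] <- 1
  cbind(tx / nn, ty / nn)
}

#' Extract the surface sampling band (10-25 px off the root)
#'
#' Band pixels are the medium pixels whose exact Euclidean distance to
#' the root mask lies in [bandMinPx, bandMaxPx]. Each pixel gets the arc
#' length (from the tip) of its nearest midline point, a side label from
#' the sign of the cross product of the local shootward tangent with the
#' midline-to-pixel displacement, and background-subtracted intensities
#' (negatives clamped to 0).
#'
#' @param geom a \code{RootGeometry}.
#' @param i488,i405 the frame's channel matrices.
#' @param config a \code{RunConfig}.
#' @return a \code{SurfaceBand}.
#' @export
extractSurfaceBand <- function(geom, i488, i405, config = runConfig()) {
  mask <- geom@mask
  D <- EBImage::distmap((!mask) * 1)
  sel <- which(!mask & D >= config@bandMinPx & D <= config@bandMaxPx,
               arr.ind = TRUE)
  if (!nrow(sel))
    rzStop("surface band is empty", "empty_band")
  px <- sel[, 2]; py <- sel[, 1]
  ml <- geom@midline
  idx <- nearestMidlineIndex(px, py, ml)
  tg <- midlineTangents(ml)
  vx <- px - ml[idx, 1]
  vy <- py - ml[idx, 2]
  crossp <- tg[idx, 1] * vy - tg[idx, 2] * vx
  side <- ifelse(crossp < 0, "left", "right")
  v488 <- i488[cbind(py, px)] - config@background488
  v405 <- i405[cbind(py, px)] - config@background405
  nClamp <- sum(v488 < 0) + sum(v405 < 0)
  if (nClamp > 0)
    rzLog(sprintf("clamped %d negative background-subtracted values", nClamp))
  v488[v488 < 0] <- 0
  v405[v405 < 0] <- 0
  sUm <- geom@arcLengthUm[idx]
  ## warn when the band is clipped by the field border over much of the root
  ny <- nrow(mask); nx <- ncol(mask)
  onBorder <- px == 1 | px == nx | py == 1 | py == ny
  if (any(onBorder)) {
    binLenUm <- config@binLengthPx * geom@pixelSize
    frac <- length(unique(floor(sUm[onBorder] / binLenUm))) /
      max(1, length(unique(floor(sUm / binLenUm))))
    if (frac > 0.3)
      rzWarn(sprintf(
        "surface band clipped by the image border over %.0f%% of the root length",
        100 * frac), class = "boundary")
  }
  pixels <- data.frame(x = px, y = py, distPx = as.numeric(D[sel]),
                       sUm = sUm, side = side, vx = vx, vy = vy,
                       I488 = v488, I405 = v405, stringsAsFactors = FALSE)
  new("SurfaceBand", pixels = pixels, bandMinPx = config@bandMinPx,
      bandMaxPx = config@bandMaxPx, pixelSize = geom@pixelSize)
}
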
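## External formats: multi-page float TIFF stacks (+ JSON sidecar),
## profile / calibration / penetration CSV tables, YAML config.
##
## TIFF layout: pages are frame-major, channels interleaved within each
## frame in the order given by channel_order (default 488 then 405).
## Intensities are stored as 32-bit floats divided by a power-of-two
## scale recorded in the sidecar, so write/read round trips are exact.

sidecarPath <- function(path) paste0(path, ".json")

## Minimal multi-page 32-bit IEEE-float grayscale TIFF writer
## (little-endian, one strip per page, SampleFormat = 3). The installed
## TIFF library reads float TIFFs but only writes unsigned-integer
## samples with lossy [0,1] quantization, which would break exact
## stack round trips; reading stays with tiff::readTIFF.
writeFloatTIFF <- function(pages, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) rzStop(
                    paste0("cannot open '", path, "' for writing"), "io"))
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  n <- length(pages)
  sizes <- vapply(pages, function(p) length(p) * 4L, integer(1))
  dataOff <- 8L + c(0L, cumsum(sizes))[seq_len(n)]
  ifdOff <- 8L + sum(sizes)
  w4(ifdOff)
  for (p in pages)
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  nE <- 10L
  ifdSize <- 2L + nE * 12L + 4L
  for (i in seq_len(n)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    entry <- function(tag, type, count, val) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(val); w2(0L) } else w4(val)
    }
    w2(nE)
    entry(256L, 4L, 1L, w)            # ImageWidth
    entry(257L, 4L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, dataOff[i])   # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 4L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, sizes[i])     # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    w4(if (i < n) ifdOff + i * ifdSize else 0L)
  }
  invisible(path)
}

#' Write a ChannelStack to a multi-page float TIFF
#'
#' Pages are interleaved (frame 1 channel 488, frame 1 channel 405,
#' frame 2 channel 488, ...) and stored as 32-bit IEEE floats; spatial
#' and temporal metadata go to a JSON sidecar (\code{<path>.json}).
#' A stack of float32-representable intensities (as produced by
#' [makePhantom()]) round-trips bit-identically.
#'
#' @param stack a \code{ChannelStack}.
#' @param path output TIFF path.
#' @return invisibly, the sidecar metadata list.
#' @seealso [loadStack()]
#' @export
saveStack <- function(stack, path) {
  stopifnot(is(stack, "ChannelStack"))
  pages <- list()
  for (t in seq_len(nFrames(stack))) {
    fr <- getFrame(stack, t)
    pages[[2 * t - 1]] <- fr$I488
    pages[[2 * t]] <- fr$I405
  }
  writeFloatTIFF(pages, path)
  meta <- list(
    format = "rhizopH-stack", version = 1L,
    n_frames = nFrames(stack), channel_order = c("488", "405"),
    pixel_size_um = stack@pixelSize,
    frame_interval_min = stack@frameInterval,
    gravity = as.numeric(stack@gravity),
    intensity_scale = 1)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(meta)
}

#' Read a two-excitation-channel TIFF stack
#'
#' Accepts a single multi-page TIFF with an even page count (frame-major,
#' channels interleaved) or a pair of single-channel TIFF paths (488
#' first, 405 second, unless \code{channelOrder} says otherwise). A JSON
#' sidecar written by [saveStack()] supplies metadata; otherwise the
#' arguments are used, and a missing pixel size falls back to 1 um/px
#' with a warning (positions are then effectively in px).
#'
#' Channels are identified purely by \code{channelOrder}, never by
#' intensity heuristics, because acquisition order differs between
#' instruments.
#'
#' @param path TIFF path, or character vector of two single-channel paths.
#' @param config a \code{RunConfig} (reserved for future use; the
#'   photometric fields live there).
#' @param pixelSize,frameInterval,gravity metadata fallbacks when no
#'   sidecar is present.
#' @param channelOrder order of channels within a frame, a permutation of
#'   \code{c("488", "405")}.
#' @return a \code{ChannelStack}.
#' @export
loadStack <- function(path, config = runConfig(), pixelSize = NA_real_,
                      frameInterval = NA_real_, gravity = c(0, 1),
                      channelOrder = c("488", "405")) {
  if (!all(sort(channelOrder) == c("405", "488")))
    rzStop("channelOrder must be a permutation of c('488','405')", "structural")
  readOne <- function(p) {
    if (!file.exists(p)) rzStop(paste0("file not found: ", p), "io")
    tryCatch(tiff::readTIFF(p, all = TRUE, as.is = FALSE),
             error = function(e) rzStop(
               paste0("unreadable TIFF '", p, "': ", conditionMessage(e)),
               "format"))
  }
  scale <- 1
  meta <- NULL
  if (length(path) == 2L) {
    pagesA <- readOne(path[1]); pagesB <- readOne(path[2])
    if (length(pagesA) != length(pagesB))
      rzStop("the two single-channel files have different frame counts",
             "structural")
    pages <- vector("list", 2L * length(pagesA))
    pages[seq(1, length(pages), 2)] <- pagesA
    pages[seq(2, length(pages), 2)] <- pagesB
    scPath <- sidecarPath(path[1])
  } else {
    pages <- readOne(path)
    if (length(pages) %% 2L != 0L)
      rzStop(paste0("odd page count (", length(pages),
                    "): the 405 nm channel is missing its pages ",
                    "(expected interleaved 488/405 pairs)"), "structural")
    scPath <- sidecarPath(path)
  }
  if (file.exists(scPath)) {
    meta <- jsonlite::read_json(scPath, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    if (!is.null(meta$pixel_size_um) && is.na(pixelSize))
      pixelSize <- meta$pixel_size_um
    if (!is.null(meta$frame_interval_min) && is.na(frameInterval))
      frameInterval <- as.numeric(meta$frame_interval_min)
    if (!is.null(meta$gravity)) gravity <- as.numeric(meta$gravity)
    if (!is.null(meta$channel_order)) channelOrder <- meta$channel_order
  }
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    rzStop("page dimensions differ between channels/frames", "structural")
  if (is.na(pixelSize)) {
    rzWarn("pixel size not available; defaulting to 1 um/px (positions in px)")
    pixelSize <- 1
  }
  nT <- length(pages) / 2L
  idx488 <- which(channelOrder == "488")
  idx405 <- which(channelOrder == "405")
  i488 <- lapply(seq_len(nT), function(t) pages[[2 * (t - 1) + idx488]] * scale)
  i405 <- lapply(seq_len(nT), function(t) pages[[2 * (t - 1) + idx405]] * scale)
  channelStack(i488, i405, pixelSize = pixelSize,
               frameInterval = frameInterval, gravity = gravity,
               meta = if (is.null(meta)) list() else meta)
}

#' Write a PHProfile to CSV
#'
#' Columns: position_um, side, n_pixels, mean_ratio, sd_ratio, pH, valid.
#' The pH column is empty unless the profile was calibrated. Numbers are
#' written at full double precision; a comment line carries the bin
#' length, pixel size and calibration flag so [loadProfile()] restores
#' the object exactly.
#'
#' @param profile a non-empty \code{PHProfile}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
saveProfile <- function(profile, path) {
  stopifnot(is(profile, "PHProfile"))
  b <- profile@bins
  if (!nrow(b)) rzStop("refusing to write an empty profile", "empty_profile")
  con <- tryCatch(file(path, "w"),
                  error = function(e) rzStop(
                    paste0("cannot open '", path, "' for writing"), "io"))
  on.exit(close(con))
  writeLines(sprintf("# rhizopH profile; bin_um=%.17g; pixel_size_um=%.17g; calibrated=%s",
                     profile@binUm, profile@pixelSize,
                     ifelse(profile@calibrated, "true", "false")), con)
  writeLines("position_um,side,n_pixels,mean_ratio,sd_ratio,pH,valid", con)
  lines <- paste(fmtNum(b$positionUm), b$side, b$nPixels,
                 fmtNum(b$meanRatio), fmtNum(b$sdRatio), fmtNum(b$pH),
                 ifelse(b$valid, "true", "false"), sep = ",")
  writeLines(lines, con)
  invisible(path)
}

#' Read a PHProfile CSV written by [saveProfile()]
#'
#' @param path CSV path.
#' @return a \code{PHProfile}.
#' @export
loadProfile <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  hdr <- readLines(path, n = 1L)
  binUm <- 1; px <- 1; calibrated <- FALSE
  if (grepl("^# rhizopH profile", hdr)) {
    gv <- function(key) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^;]+)"), hdr))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    binUm <- as.numeric(gv("bin_um"))
    px <- as.numeric(gv("pixel_size_um"))
    calibrated <- identical(gv("calibrated"), "true")
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bins <- data.frame(
    positionUm = as.numeric(d$position_um), side = as.character(d$side),
    nPixels = as.integer(d$n_pixels), meanRatio = as.numeric(d$mean_ratio),
    sdRatio = as.numeric(d$sd_ratio), pH = as.numeric(d$pH),
    valid = d$valid %in% c("true", "TRUE", TRUE),
    stringsAsFactors = FALSE)
  new("PHProfile", bins = bins, binUm = binUm, pixelSize = px,
      calibrated = calibrated)
}

#' Read a calibration standards CSV
#'
#' Expects columns \code{pH} and \code{ratio}; rows sharing a pH value
#' are averaged, and at least 3 distinct pH values are required.
#'
#' @param path CSV path.
#' @return data.frame (pH, ratio) sorted by pH.
#' @export
loadCalibrationTable <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) rzStop(
                  paste0("cannot parse '", path, "'"), "parse"))
  if (!all(c("pH", "ratio") %in% names(d)))
    rzStop("calibration table needs columns pH, ratio", "parse")
  pH <- suppressWarnings(as.numeric(d$pH))
  ratio <- suppressWarnings(as.numeric(d$ratio))
  if (anyNA(pH) || anyNA(ratio))
    rzStop("non-numeric cells in calibration table", "parse")
  agg <- stats::aggregate(list(ratio = ratio), by = list(pH = pH), FUN = mean)
  agg <- agg[order(agg$pH), , drop = FALSE]
  rownames(agg) <- NULL
  if (nrow(agg) < 3)
    rzStop(sprintf("need >= 3 distinct pH standards, got %d", nrow(agg)),
           "insufficient_standards")
  agg
}

#' Write calibration standards to CSV
#' @param standards data.frame with columns pH, ratio.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
saveCalibrationTable <- function(standards, path) {
  stopifnot(all(c("pH", "ratio") %in% names(standards)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("pH,ratio", con)
  writeLines(paste(fmtNum(standards$pH), fmtNum(standards$ratio), sep = ","),
             con)
  invisible(path)
}

#' Read a mesh penetration-count table
#'
#' Columns: genotype, pore_size_um, n_penetrated, n_total, replicate.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
loadPenetrationTable <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "pore_size_um", "n_penetrated", "n_total", "replicate")
  if (!all(need %in% names(d)))
    rzStop(paste0("penetration table needs columns ",
                  paste(need, collapse = ", ")), "parse")
  if (any(d$n_penetrated < 0) || any(d$n_penetrated > d$n_total))
    rzStop("require 0 <= n_penetrated <= n_total", "parse")
  d
}

#' Write a penetration-count table to CSV
#' @param table data.frame as in [loadPenetrationTable()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
savePenetrationTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a RunConfig from YAML
#'
#' Field names mirror [runConfig()] arguments.
#'
#' @param path YAML path.
#' @return a \code{RunConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) rzStop(paste0("file not found: ", path), "io")
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    rzStop(paste0("unknown config fields: ", paste(bad, collapse = ", ")),
           "parse")
  do.call(runConfig, y)
}

#' Write a RunConfig to YAML
#' @param config a \code{RunConfig}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
saveConfig <- function(config, path) {
  fields <- names(formals(runConfig))
  vals <- lapply(fields, function(f) slot(config, f))
  names(vals) <- fields
  vals$seed <- if (is.na(vals$seed)) NULL else vals$seed
  yaml::write_yaml(vals, path)
  invisible(path)
}

## JSON writer shared by kinetics / CLI outputs.
writeResultJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
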
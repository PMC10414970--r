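## Internal helpers: structured conditions, float32 snapping, logging.

rzStop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("rhizopH_", class), "rhizopH_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

rzWarn <- function(msg, class = "warning") {
  warning(structure(
    class = c(paste0("rhizopH_", class), "rhizopH_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Round numeric values to the nearest IEEE single-precision float
#'
#' Stacks are stored on disk as 32-bit float TIFF pages. Snapping
#' intensities onto the float32 grid at generation time makes write/read
#' round trips bit-identical.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with float32-representable values.
#' @export
asFloat32 <- function(x) {
  v <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}

rzLog <- function(..., verbose = getOption("rhizopH.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[rhizopH] ", ...)
  invisible(NULL)
}

## Unit-normalize a 2-vector.
unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) rzStop("zero-length vector cannot be normalized", "degenerate")
  v / n
}

## Angle in degrees between two 2D vectors (unsigned, [0, 180]).
vecAngleDeg <- function(a, b) {
  a <- unitVec(a); b <- unitVec(b)
  d <- max(-1, min(1, sum(a * b)))
  acos(d) * 180 / pi
}

## Run code with a locally-set RNG seed, restoring global state after.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Format numerics for CSV at full double precision.
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
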
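## Colour map rendering ------------------------------------------------------
##
## All renderers return H x W x 3 numeric arrays in [0, 1] (writePNG-ready).
## Conventions: overlay maps show agreement in yellow, test-only signal in
## magenta, reference-only in cyan, background black; confidence maps sweep
## hue from red (0) to cyan (1) with brightness carrying image intensity;
## the artefact scale map sweeps red (finest scale) to purple (coarsest),
## grey where confidence is never reached.

#' Test/reference overlay map
#'
#' Red channel carries the test image, green the reference, blue their
#' absolute difference: agreement renders yellow, test-only magenta,
#' reference-only cyan, background black.  Works on binary masks
#' (sharpening map) and on intensity grids (structure map), where partial
#' overlap grades continuously.
#'
#' @param test,ref Logical masks or numeric matrices in `[0, 1]`, same
#'   dimensions.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlay_map <- function(test, ref) {
  if (is.logical(test)) test <- test * 1.0
  if (is.logical(ref)) ref <- ref * 1.0
  if (!identical(dim(test), dim(ref))) stop("shape mismatch")
  rgb <- array(0, c(nrow(test), ncol(test), 3L))
  rgb[, , 1L] <- test
  rgb[, , 2L] <- ref
  rgb[, , 3L] <- abs(test - ref)
  rgb[rgb > 1] <- 1
  rgb
}

#' Confidence colour map
#'
#' Hue interpolates red (score 0) to cyan (score 1); the value channel is
#' the combined input intensity, so background (zero combined intensity)
#' stays black regardless of score.  Pixels without a defined score (`NA`)
#' are rendered grey at the combined brightness.
#'
#' @param combined Numeric matrix in `[0, 1]`: normalised sum of the
#'   blurred test and reference images.
#' @param s_conf Confidence matrix in `[0, 1]` (`NA` = no evidence).
#' @return `H x W x 3` RGB array.
#' @export
confidence_map <- function(combined, s_conf) {
  if (!identical(dim(combined), dim(s_conf))) stop("shape mismatch")
  v <- clamp01(combined)
  s <- clamp01(s_conf)
  hue <- s * 0.5                       # 0 = red ... 0.5 = cyan
  na <- is.na(s)
  hue[na] <- 0
  sat <- matrix(1, nrow(s), ncol(s))
  sat[na] <- 0                         # no-evidence pixels render grey
  cols <- grDevices::hsv(h = as.vector(hue), s = as.vector(sat),
                         v = as.vector(v))
  dim3_from_cols(cols, dim(combined))
}

#' Render an artefact scale map to RGB
#'
#' Hue runs red (scale 1, finest) to purple (the maximum scale, coarsest);
#' brightness is the combined input intensity.  Pixels that never reach the
#' confidence threshold are grey.
#'
#' @param x An [artefact_scale_map].
#' @return `H x W x 3` RGB array.
#' @export
render_artefact_map <- function(x) {
  stopifnot(inherits(x, "artefact_scale_map"))
  v <- clamp01(x$combined)
  frac <- (x$scale - 1) / max(1L, x$max_scale_no - 1L)
  hue <- frac * (270 / 360)            # red -> purple sweep
  na <- is.na(hue)
  hue[na] <- 0
  sat <- matrix(1, nrow(v), ncol(v))
  sat[na] <- 0
  cols <- grDevices::hsv(h = as.vector(hue), s = as.vector(sat),
                         v = as.vector(v))
  dim3_from_cols(cols, dim(v))
}

# NA-safe clamp to [0, 1] that preserves matrix dimensions
clamp01 <- function(m) {
  m[which(m < 0)] <- 0
  m[which(m > 1)] <- 1
  m
}

dim3_from_cols <- function(cols, d) {
  m <- t(grDevices::col2rgb(cols)) / 255
  array(c(m[, 1L], m[, 2L], m[, 3L]), c(d[1], d[2], 3L))
}

#' Write an RGB array or binary mask as 8-bit PNG
#'
#' Binary masks are written as 0/255 grayscale.
#' @param x RGB array in `[0, 1]`, numeric matrix, or logical mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(x, path) {
  if (is.logical(x)) x <- x * 1.0
  x[x > 1] <- 1; x[x < 0] <- 0
  png::writePNG(x, path)
  invisible(path)
}
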
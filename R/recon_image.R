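#' Reconstruction image container
#'
#' A `recon_image` bundles a 2D grid of non-negative intensities with the
#' physical size of its pixels.  It is the unit every input to the
#' multi-scale comparison is reduced to: loaded TIFF/PNG reconstructions and
#' rendered localisation tables alike.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities
#'   (arbitrary units; rows index y, columns index x).
#' @param pixel_size_nm Positive scalar, the physical side of one
#'   reconstruction pixel in nanometres (typically 10--20 nm).
#' @param name Free-text label carried through to outputs.
#' @return An object of class `recon_image` with fields `pixels`,
#'   `pixel_size_nm` and `name`.
#' @examples
#' img <- recon_image(matrix(runif(64), 8, 8), pixel_size_nm = 10)
#' img
#' @export
recon_image <- function(pixels, pixel_size_nm, name = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must all be finite")
  bad <- which(pixels < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(pixels))
    stop(sprintf("negative intensity at pixel (row %d, col %d)", rc[1], rc[2]))
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a positive scalar")
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         name = as.character(name)[1L]),
    class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<recon_image> '%s': %d x %d px @ %g nm/px (%.3g x %.3g um)\n",
              x$name, d[1], d[2], x$pixel_size_nm,
              d[2] * x$pixel_size_nm / 1000, d[1] * x$pixel_size_nm / 1000))
  cat(sprintf("  intensity range [%g, %g], %d nonzero px\n",
              min(x$pixels), max(x$pixels), sum(x$pixels > 0)))
  invisible(x)
}

#' @export
dim.recon_image <- function(x) dim(x$pixels)

is_recon_image <- function(x) inherits(x, "recon_image")

## coerce matrices on the fly so internal helpers compose easily
as_recon <- function(x, pixel_size_nm = 1, name = "image") {
  if (is_recon_image(x)) x else recon_image(x, pixel_size_nm, name)
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop(sprintf("images differ in size: %s vs %s",
                 paste(dim(a$pixels), collapse = "x"),
                 paste(dim(b$pixels), collapse = "x")))
  if (!isTRUE(all.equal(a$pixel_size_nm, b$pixel_size_nm)))
    stop("images differ in pixel_size_nm")
  invisible(TRUE)
}

# PNG IHDR bit depth lives at a fixed offset: 8-byte signature, 8-byte chunk
# header, 4+4 bytes width/height, then one bit-depth byte.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("truncated PNG file: ", path)
  as.integer(hdr[25L])
}

#' Load a reconstruction image from TIFF or PNG
#'
#' Reads a single-channel 2D reconstruction.  Stored integer encodings are
#' returned on their native scale (a 16-bit PNG with maximum value 65535
#' loads as 65535, not 1.0).  Multi-channel inputs are converted to
#' luminance (Rec. 709 weights) with a warning; multi-page TIFFs use the
#' first page only, with a warning.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_nm Reconstruction pixel size in nm.
#' @param name Label; defaults to the file name.
#' @return A [recon_image].
#' @export
load_reconstruction <- function(path, pixel_size_nm, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # as.is keeps integer encodings on their stored scale; float TIFFs are
    # always read as-is and reject the flag
    px <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e) {
                     if (grepl("floating point", conditionMessage(e)))
                       tiff::readTIFF(path, all = TRUE)
                     else stop(e)
                   })
    if (is.list(px)) {
      if (length(px) > 1L)
        warning("multi-page TIFF: using first page only (", length(px),
                " pages in ", basename(path), ")")
      px <- px[[1L]]
    }
  } else if (ext == "png") {
    depth <- png_bit_depth(path)
    px <- png::readPNG(path)
    # readPNG rescales to [0,1]; restore the stored integer scale
    px <- px * (2^depth - 1)
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3L]
    warning("multi-channel image (", nc, " channels): converting to luminance")
    if (nc >= 3L) {
      px <- 0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
    } else {
      px <- px[, , 1L]
    }
  }
  if (length(dim(px)) != 2L) stop("not a 2D image: ", path)
  recon_image(px, pixel_size_nm, name = name)
}

#' Write a reconstruction image to TIFF or PNG
#'
#' TIFF output is single-strip 32-bit IEEE float, so intensities are stored
#' on their native scale (values already representable in single precision,
#' e.g. localisation counts, round-trip bit-identically).  PNG output is
#' scaled to the image maximum.
#'
#' @param img A [recon_image].
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(img, path) {
  stopifnot(is_recon_image(img))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_float_tiff(img$pixels, path)
  } else if (ext == "png") {
    mx <- max(img$pixels)
    scaled <- if (mx > 0) img$pixels / mx else img$pixels
    png::writePNG(scaled, path)
  } else stop("unsupported output format '", ext, "'")
  invisible(path)
}

# Minimal single-strip grayscale float32 TIFF writer (little-endian).
# The tiff package reads float TIFFs but only writes [0,1]-scaled integer
# samples, which cannot carry raw reconstruction intensities.
write_float_tiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: byte order II, magic 42, IFD at offset 8
  writeBin(charToRaw("II"), con)
  wr2(42L); wr4(8L)
  tags <- list(  # (tag, type, value); type 3 = SHORT, 4 = LONG
    c(256L, 4L, w),            # ImageWidth
    c(257L, 4L, h),            # ImageLength
    c(258L, 3L, 32L),          # BitsPerSample
    c(259L, 3L, 1L),           # Compression: none
    c(262L, 3L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 0L),           # StripOffsets (patched below)
    c(277L, 3L, 1L),           # SamplesPerPixel
    c(278L, 4L, h),            # RowsPerStrip
    c(279L, 4L, 4L * w * h),   # StripByteCounts
    c(284L, 3L, 1L),           # PlanarConfiguration
    c(339L, 3L, 3L))           # SampleFormat: IEEE float
  data_off <- 8L + 2L + 12L * length(tags) + 4L
  wr2(length(tags))
  for (tg in tags) {
    v <- if (tg[1] == 273L) data_off else tg[3]
    wr2(tg[1]); wr2(tg[2]); wr4(1L)
    if (tg[2] == 3L) { wr2(v); wr2(0L) } else wr4(v)
  }
  wr4(0L)  # no further IFD
  # pixel data, row-major
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' Cap hot pixels at an intensity percentile
#'
#' Repeated localisations of a single blinking fluorophore produce very
#' bright isolated pixels that destabilise adaptive thresholding.  The
#' intensity histogram of the nonzero pixels is therefore capped at its 98th
#' percentile (zero-valued background pixels are excluded from the histogram
#' and remain zero).
#'
#' @param img A [recon_image] with at least one nonzero pixel.
#' @param percentile Percentile in (0, 100] of the nonzero-intensity
#'   distribution at which to cap; default 98.  Linear-interpolation
#'   (type 7) percentile.
#' @return A capped copy of `img`.
#' @export
flatten_intensity <- function(img, percentile = 98) {
  stopifnot(is_recon_image(img))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100)
    stop("'percentile' must lie in (0, 100]")
  nz <- img$pixels[img$pixels > 0]
  if (!length(nz)) stop("all-zero image: no structure to assess")
  cap <- stats::quantile(nz, percentile / 100, names = FALSE, type = 7)
  out <- img
  out$pixels <- pmin(img$pixels, cap)
  out
}

#' Normalise an image to unit maximum intensity
#'
#' @param img A [recon_image] with positive maximum.
#' @return Copy of `img` with intensities divided by the maximum (max
#'   becomes exactly 1).
#' @export
normalise_max <- function(img) {
  stopifnot(is_recon_image(img))
  mx <- max(img$pixels)
  if (mx <= 0) stop("all-zero image: cannot normalise")
  out <- img
  out$pixels <- img$pixels / mx
  out
}
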
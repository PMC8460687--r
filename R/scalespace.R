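## Separable convolution helpers -------------------------------------------
##
## All windowed operations (Gaussian blur, box means for Wellner
## thresholding, local-correlation moments) are separable shift-and-add
## convolutions on the image matrix.  Borders use truncated-window
## renormalisation: the zero-padded convolution is divided by the same
## convolution of an all-ones matrix, so a border pixel is averaged over its
## in-bounds support only.  This avoids phantom dark frames that would
## otherwise binarise as spurious structure at large blur scales.

# 1D convolution along matrix rows (vertical direction), zero padding
conv_cols <- function(m, k) {
  n <- nrow(m); p <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, n + 2L * p, ncol(m))
  pad[(p + 1L):(p + n), ] <- m
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * pad[(i):(i + n - 1L), , drop = FALSE]
  out
}

conv_sep <- function(m, k) t(conv_cols(t(conv_cols(m, k)), k))

# renormalised separable convolution (kernel assumed symmetric, odd length)
conv_sep_norm <- function(m, k) {
  ones <- matrix(1, nrow(m), ncol(m))
  conv_sep(m, k) / conv_sep(ones, k)
}

# truncated-window box sum and in-bounds counts for window side w (odd)
box_sum <- function(m, w) {
  if (w <= 1L) return(m)
  conv_sep(m, rep(1, w))
}
box_count <- function(nr, nc, w) {
  if (w <= 1L) return(matrix(1, nr, nc))
  conv_sep(matrix(1, nr, nc), rep(1, w))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# symmetric Gaussian kernel for a given FWHM in pixels, truncated at 4 sigma
gaussian_kernel_fwhm <- function(fwhm_px) {
  sigma <- fwhm_to_sigma(fwhm_px)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## Scale specification -------------------------------------------------------

#' Length-scale specification
#'
#' One analysis length scale.  Scale number `s` means a Gaussian blur of
#' FWHM `s` reconstruction pixels; the Wellner neighbourhood radius is
#' `r = ceil(s / 2) - 1`, so that the window side `2r + 1` is the largest
#' odd number of pixels not greater than the scale.  `r_prime` is the same
#' radius evaluated at half the instrument-PSF scale, used by the auxiliary
#' smoothing term of the adaptive threshold.
#'
#' @param scale_no Integer scale number >= 1.
#' @param pixel_size_nm Reconstruction pixel size (nm).
#' @param psf_scale_no Instrument PSF FWHM in reconstruction pixels
#'   (integer >= 1).
#' @return An object of class `scale_spec` with fields `scale_no`,
#'   `fwhm_px`, `fwhm_nm`, `sigma_px`, `r`, `r_prime`.
#' @export
scale_spec <- function(scale_no, pixel_size_nm = 1, psf_scale_no = scale_no) {
  scale_no <- as.integer(scale_no)
  psf_scale_no <- as.integer(psf_scale_no)
  if (scale_no < 1L) stop("'scale_no' must be >= 1")
  if (psf_scale_no < 1L) stop("'psf_scale_no' must be >= 1")
  structure(
    list(scale_no = scale_no,
         fwhm_px = as.numeric(scale_no),
         fwhm_nm = scale_no * pixel_size_nm,
         sigma_px = fwhm_to_sigma(scale_no),
         r = wellner_radius(scale_no),
         r_prime = wellner_radius(psf_scale_no)),
    class = "scale_spec")
}

#' Wellner neighbourhood radius for a scale number
#'
#' `r = ceil(scale_no / 2) - 1`; the window side `2r + 1` is the largest odd
#' integer not exceeding `scale_no`.
#' @param scale_no Integer scale number >= 1.
#' @return Integer radius >= 0.
#' @export
wellner_radius <- function(scale_no) as.integer(ceiling(scale_no / 2) - 1)

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> No. %d: FWHM %g px (%g nm), sigma %.3f px, r=%d, r'=%d\n",
              x$scale_no, x$fwhm_px, x$fwhm_nm, x$sigma_px, x$r, x$r_prime))
  invisible(x)
}

#' Adaptive-threshold parameter set
#'
#' Coefficients of the Wellner-style adaptive threshold
#' `thr = C_b * mean_r(P) + 0.1 * mean_r'(P) + C_a`:
#' the proportion `C_b` of the local mean (0.7 for the sharpening map, 0.85
#' for the structure map), the baseline noise floor `C_a` (0.04 / 0.02), the
#' auxiliary coefficient 0.1 applied to the local mean at half the PSF
#' scale, and the PSF scale number itself.
#'
#' @param c_b_sharp,c_b_struct Local-mean proportions; the structure value
#'   must not be below the sharpening value.
#' @param c_a_sharp,c_a_struct Baseline threshold contributions (>= 0).
#' @param aux_coeff Coefficient of the PSF-neighbourhood mean term (>= 0).
#' @param psf_scale_no Instrument PSF FWHM in reconstruction pixels.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(c_b_sharp = 0.7, c_b_struct = 0.85,
                             c_a_sharp = 0.04, c_a_struct = 0.02,
                             aux_coeff = 0.1, psf_scale_no = 27L) {
  if (c_b_sharp <= 0) stop("'c_b_sharp' must be positive")
  if (c_b_struct < c_b_sharp)
    stop("structure threshold coefficient must not be below the sharpening one")
  if (c_a_sharp < 0 || c_a_struct < 0) stop("baseline C_a must be >= 0")
  if (aux_coeff < 0) stop("'aux_coeff' must be >= 0")
  psf_scale_no <- as.integer(psf_scale_no)
  if (psf_scale_no < 1L) stop("'psf_scale_no' must be >= 1")
  structure(list(c_b_sharp = c_b_sharp, c_b_struct = c_b_struct,
                 c_a_sharp = c_a_sharp, c_a_struct = c_a_struct,
                 aux_coeff = aux_coeff, psf_scale_no = psf_scale_no),
            class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf(paste0("<threshold_params> sharpening C_b=%g C_a=%g | ",
                     "structure C_b=%g C_a=%g | aux=%g @ PSF scale %d\n"),
              x$c_b_sharp, x$c_a_sharp, x$c_b_struct, x$c_a_struct,
              x$aux_coeff, x$psf_scale_no))
  invisible(x)
}

## Per-scale operations ------------------------------------------------------

#' Gaussian blur by FWHM
#'
#' Isotropic Gaussian convolution whose FWHM equals the scale's length in
#' pixels.  Kernel truncated at 4 sigma; borders use truncated-window
#' renormalisation so a constant image stays constant.
#'
#' @param img A [recon_image] (or plain matrix).
#' @param scale A [scale_spec], or an integer scale number.
#' @return Blurred image of the same class as the input.
#' @export
gaussian_blur_fwhm <- function(img, scale) {
  s <- if (inherits(scale, "scale_spec")) scale$scale_no else as.integer(scale)
  if (s < 1L) stop("scale number must be >= 1")
  k <- gaussian_kernel_fwhm(s)
  if (is_recon_image(img)) {
    out <- img
    out$pixels <- conv_sep_norm(img$pixels, k)
    out
  } else conv_sep_norm(img, k)
}

#' Neighbourhood (window) mean
#'
#' Mean intensity over the `(2 radius + 1)^2` window centred on each pixel;
#' at borders the mean is taken over in-bounds pixels only.  Radius 0 is the
#' identity.
#'
#' @param img A [recon_image] or matrix.
#' @param radius Integer window radius >= 0.
#' @return Matrix of window means.
#' @export
neighbourhood_mean <- function(img, radius) {
  m <- if (is_recon_image(img)) img$pixels else img
  radius <- as.integer(radius)
  if (radius < 0L) stop("'radius' must be >= 0")
  if (radius == 0L) return(m)
  w <- 2L * radius + 1L
  box_sum(m, w) / box_count(nrow(m), ncol(m), w)
}

#' Adaptive (Wellner) threshold surface
#'
#' Per-pixel threshold
#' `thr = C_b * mean_r(P) + aux * mean_r'(P) + C_a`, where `mean_r` is the
#' window mean at the current scale's neighbourhood radius and `mean_r'` the
#' window mean at half the PSF scale.  The `(C_b, C_a)` pair is selected by
#' `which`: sharpening (0.7, 0.04 by default) or structure (0.85, 0.02).
#' The input is expected to be flattened, blurred at `scale`, and normalised
#' to maximum 1.
#'
#' @param img A [recon_image] or matrix (blurred, max-normalised).
#' @param scale A [scale_spec].
#' @param params A [threshold_params].
#' @param which `"sharpening"` or `"structure"`.
#' @return Matrix of per-pixel thresholds.
#' @export
adaptive_threshold <- function(img, scale, params = threshold_params(),
                               which = c("sharpening", "structure")) {
  which <- match.arg(which)
  m <- if (is_recon_image(img)) img$pixels else img
  c_b <- if (which == "sharpening") params$c_b_sharp else params$c_b_struct
  c_a <- if (which == "sharpening") params$c_a_sharp else params$c_a_struct
  c_b * neighbourhood_mean(m, scale$r) +
    params$aux_coeff * neighbourhood_mean(m, scale$r_prime) +
    c_a
}

#' Binarise an image against a threshold surface
#'
#' Strict comparison: a pixel is foreground iff its intensity exceeds the
#' threshold, so an all-zero background never binarises as structure when
#' `C_a > 0`.
#'
#' @param img A [recon_image] or matrix.
#' @param thr Threshold matrix of the same dimensions.
#' @return Logical mask matrix.
#' @export
binarise <- function(img, thr) {
  m <- if (is_recon_image(img)) img$pixels else img
  if (!identical(dim(m), dim(thr))) stop("image/threshold shape mismatch")
  m > thr
}

#' Skeletonise a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle morphological thinning of the 8-connected
#' foreground down to a one-pixel-wide medial skeleton.  Deterministic; an
#' empty mask yields an empty skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical skeleton matrix of the same dimensions.
#' @export
skeletonise <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  img <- matrix(0L, nr + 2L, nc + 2L)
  img[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- img[ri - 1L, ci];      p3 <- img[ri - 1L, ci + 1L]
      p4 <- img[ri, ci + 1L];      p5 <- img[ri + 1L, ci + 1L]
      p6 <- img[ri + 1L, ci];      p7 <- img[ri + 1L, ci - 1L]
      p8 <- img[ri, ci - 1L];      p9 <- img[ri - 1L, ci - 1L]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- if (step == 1L) {
        (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      del <- img[ri, ci] == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        sub <- img[ri, ci]
        sub[del] <- 0L
        img[ri, ci] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[ri, ci] == 1L
}

#' Re-blur a skeleton at the current length scale
#'
#' The one-pixel skeletons of two very similar structures can disagree by
#' single-pixel displacements; blurring each skeleton with a Gaussian of
#' FWHM equal to the current length scale makes their overlap substantial
#' unless the structures differ by about the current scale or more.  The
#' result is normalised to maximum 1 (an empty skeleton stays all zero).
#'
#' @param skel Logical skeleton matrix.
#' @param scale A [scale_spec] or integer scale number.
#' @return Numeric matrix in `[0, 1]`.
#' @export
reblur_skeleton <- function(skel, scale) {
  m <- gaussian_blur_fwhm(skel * 1.0, scale)
  mx <- max(m)
  if (mx > 0) m / mx else m
}
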
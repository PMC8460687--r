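test_that("scale radii follow the largest-odd-window rule", {
  for (s in 1:40) {
    r <- wellner_radius(s)
    w <- 2L * r + 1L
    expect_true(w %% 2L == 1L && w <= s || s == 1L && w == 1L)
    expect_true(w <= max(s, 1L))
    expect_true(w + 2L > s)               # largest such odd number
    if (s > 1L) expect_gte(r, wellner_radius(s - 1L))  # non-decreasing
  }
  sp <- scale_spec(5, pixel_size_nm = 10, psf_scale_no = 27)
  expect_equal(sp$r, 2L)
  expect_equal(sp$r_prime, 13L)
  expect_equal(sp$fwhm_nm, 50)
  expect_equal(sp$sigma_px, 5 / (2 * sqrt(2 * log(2))))
  expect_error(scale_spec(0), "scale_no")
})

test_that("gaussian blur has the requested FWHM and matches dense convolution", {
  # delta response: measure FWHM by linear interpolation of the profile
  n <- 41
  delta <- matrix(0, n, n); delta[21, 21] <- 1
  b <- gaussian_blur_fwhm(delta, scale_spec(4))
  prof <- b[21, ]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  interp <- function(i1, i2) i1 + (half - prof[i1]) / (prof[i2] - prof[i1])
  fwhm <- interp(hi, hi + 1) - interp(lo, lo - 1)
  expect_equal(fwhm, 4, tolerance = 0.1 / 4)

  # constant image invariant under renormalised borders
  cimg <- matrix(3, 16, 16)
  expect_equal(gaussian_blur_fwhm(cimg, scale_spec(6)), cimg,
               tolerance = 1e-12)

  # brute-force dense convolution oracle
  set.seed(3)
  m <- matrix(runif(32 * 32), 32, 32)
  for (s in c(2, 5)) {
    expect_lt(max(abs(gaussian_blur_fwhm(m, scale_spec(s)) -
                        oracle_gaussian_blur(m, s))), 1e-8)
  }
})

test_that("neighbourhood_mean matches the double-loop window oracle", {
  set.seed(4)
  m <- matrix(runif(16 * 16), 16, 16)
  expect_identical(neighbourhood_mean(m, 0), m)
  expect_equal(neighbourhood_mean(matrix(2.5, 9, 9), 3),
               matrix(2.5, 9, 9), tolerance = 1e-12)
  for (r in c(1, 2, 5)) {
    expect_lt(max(abs(neighbourhood_mean(m, r) - oracle_window_mean(m, r))),
              1e-12)
  }
})

test_that("adaptive threshold reproduces its closed form and the oracle", {
  params <- threshold_params(psf_scale_no = 27)
  u <- matrix(1, 30, 30)
  sp <- scale_spec(5, psf_scale_no = 27)
  expect_equal(adaptive_threshold(u, sp, params, "sharpening"),
               matrix(0.7 + 0.1 + 0.04, 30, 30), tolerance = 1e-12)
  expect_equal(adaptive_threshold(u, sp, params, "structure"),
               matrix(0.85 + 0.1 + 0.02, 30, 30), tolerance = 1e-12)

  set.seed(5)
  m <- matrix(runif(16 * 16), 16, 16)
  sp5 <- scale_spec(5, psf_scale_no = 27)
  got <- adaptive_threshold(m, sp5, params, "sharpening")
  want <- oracle_adaptive_threshold(m, sp5$r, sp5$r_prime, 0.7, 0.04, 0.1)
  expect_lt(max(abs(got - want)), 1e-12)

  # monotone in image scale: k-times brighter image, fixed C_a
  thr1 <- adaptive_threshold(m, sp5, params, "sharpening")
  thr3 <- adaptive_threshold(3 * m, sp5, params, "sharpening")
  expect_equal(thr3 - 0.04, 3 * (thr1 - 0.04), tolerance = 1e-10)
})

test_that("threshold parameter invariants are enforced", {
  expect_error(threshold_params(c_b_sharp = 0.9, c_b_struct = 0.7),
               "not be below")
  expect_error(threshold_params(c_a_sharp = -0.1))
  expect_error(threshold_params(psf_scale_no = 0))
})

test_that("binarisation is strict and separates a 40%-trough ridge pair", {
  u <- matrix(1, 10, 10)
  expect_true(all(binarise(u, matrix(0.84, 10, 10))))
  z <- matrix(0, 10, 10)
  expect_false(any(binarise(z, matrix(0.04, 10, 10))))
  expect_false(any(binarise(u, matrix(1, 10, 10))))  # strictly greater

  # ridge pair with trough at 40% of peak (peak-to-trough 2.5): sharpening
  # binarisation at the best scale yields two components
  img <- rect_ridge_pair(0.4)
  params <- threshold_params(psf_scale_no = 27)
  ncomp <- sapply(1:6, function(s) {
    sp <- scale_spec(s, 10, 27)
    b <- normalise_max(gaussian_blur_fwhm(flatten_intensity(img), sp))
    count_components(binarise(b, adaptive_threshold(b, sp, params,
                                                    "sharpening")))
  })
  expect_true(any(ncomp == 2L))
})

test_that("skeletonisation thins ribbons and disks to medial remnants", {
  expect_false(any(skeletonise(matrix(FALSE, 8, 8))))

  # 5-px-wide horizontal ribbon spanning the image -> 1-px-wide line
  rib <- matrix(FALSE, 20, 40)
  rib[8:12, ] <- TRUE
  sk <- skeletonise(rib)
  hits <- colSums(sk)
  expect_true(all(hits <= 1))             # nowhere wider than one pixel
  expect_true(all(hits[4:36] == 1))       # continuous away from end effects

  # filled disk of radius 6 -> near-point skeleton
  d <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21)
    d[i, j] <- (i - 11)^2 + (j - 11)^2 <= 36
  expect_lte(sum(skeletonise(d)), 5)

  # component count preserved for two separate blobs
  two <- matrix(FALSE, 12, 30)
  two[4:8, 3:10] <- TRUE; two[4:8, 20:27] <- TRUE
  expect_equal(count_components(skeletonise(two)), 2L)
})

test_that("re-blurred skeletons tolerate sub-scale offsets only", {
  n <- 64
  sk <- matrix(FALSE, n, n); sk[n / 2, 8:(n - 8)] <- TRUE
  shift_by <- function(k) { s <- matrix(FALSE, n, n)
                            s[n / 2 + k, 8:(n - 8)] <- TRUE; s }
  base <- reblur_skeleton(sk, scale_spec(8))
  expect_true(all(reblur_skeleton(matrix(FALSE, n, n), scale_spec(8)) == 0))
  expect_equal(max(base), 1)
  ov <- function(k) sum(base * reblur_skeleton(shift_by(k), scale_spec(8)))
  expect_gt(ov(1), 0.8 * ov(0))    # 1 px shift at scale 8: heavy overlap
  expect_lt(ov(16), 0.05 * ov(0))  # 2x FWHM shift: overlap gone
})

test_that("the per-scale pipeline is deterministic", {
  set.seed(6)
  img <- recon_image(matrix(rpois(40 * 40, 1), 40, 40) * 1.0, 10)
  once <- function() {
    sp <- scale_spec(4, 10, 27)
    b <- normalise_max(gaussian_blur_fwhm(flatten_intensity(img), sp))
    mask <- binarise(b, adaptive_threshold(b, sp, threshold_params(
      psf_scale_no = 27), "structure"))
    list(mask = mask, skel = skeletonise(mask))
  }
  expect_identical(once(), once())
})
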
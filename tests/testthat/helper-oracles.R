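# Independent brute-force oracles and fixture builders used across tests.
# Oracles are deliberately written as plain double loops over window
# indices, independent of the package's separable-convolution internals.

# window mean with border truncation, double loop
oracle_window_mean <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - radius):min(nr, i + radius)
    ci <- max(1, j - radius):min(nc, j + radius)
    out[i, j] <- mean(m[ri, ci])
  }
  out
}

oracle_adaptive_threshold <- function(m, r, r_prime, c_b, c_a, aux) {
  c_b * oracle_window_mean(m, r) + aux * oracle_window_mean(m, r_prime) + c_a
}

# textbook centred-moment Pearson correlation over truncated windows
oracle_local_pcc <- function(a, b, side) {
  half <- (side - 1) / 2
  nr <- nrow(a); nc <- ncol(a)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    ci <- max(1, j - half):min(nc, j + half)
    x <- as.vector(a[ri, ci]); y <- as.vector(b[ri, ci])
    vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
    if (vx > 1e-13 && vy > 1e-13)
      out[i, j] <- mean((x - mean(x)) * (y - mean(y))) / sqrt(vx * vy)
  }
  out
}

oracle_global_pcc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# dense 2D convolution with a truncated Gaussian kernel and the same
# in-bounds renormalisation contract as the package blur
oracle_gaussian_blur <- function(m, fwhm_px) {
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; wacc <- 0
    for (di in (-r):r) for (dj in (-r):r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        w <- k2[di + r + 1, dj + r + 1]
        acc <- acc + w * m[ii, jj]
        wacc <- wacc + w
      }
    }
    out[i, j] <- acc / wacc
  }
  out
}

# 8-connected component count via iterative frontier dilation
count_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  dilate8 <- function(m) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    out <- matrix(FALSE, nr, nc)
    for (di in 0:2) for (dj in 0:2)
      out <- out | p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
    out
  }
  left <- mask
  ncomp <- 0L
  while (any(left)) {
    ncomp <- ncomp + 1L
    comp <- matrix(FALSE, nr, nc)
    comp[which(left)[1L]] <- TRUE
    repeat {
      grown <- dilate8(comp) & left
      if (identical(grown, comp)) break
      comp <- grown
    }
    left <- left & !comp
  }
  ncomp
}

# deterministic crossing-lines image: two Gaussian-profile lines through
# the centre at +/- half the crossing angle
crossing_image <- function(n = 256, angle_deg = 40, sigma_px = 2,
                           pixel_size_nm = 10) {
  cx <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  half <- angle_deg / 2 * pi / 180
  d1 <- abs(cos(half) * (xs - cx) - sin(half) * (ys - cx))
  d2 <- abs(cos(half) * (xs - cx) + sin(half) * (ys - cx))
  px <- exp(-d1^2 / (2 * sigma_px^2)) + exp(-d2^2 / (2 * sigma_px^2))
  recon_image(px, pixel_size_nm, name = "crossing")
}

# two rectangular ridges (width W px) flanking a flat-floor gap (width g,
# depth h in [0,1]); the canonical contrast-dip-in-structure fixture
rect_ridge_pair <- function(h, W = 27, g = 6, nr = 64, nc = 160,
                            pixel_size_nm = 10) {
  x <- seq_len(nc); cx <- (nc + 1) / 2
  prof <- numeric(nc)
  prof[abs(x - cx) <= g / 2 + W] <- 1
  prof[abs(x - cx) <= g / 2] <- h
  recon_image(matrix(rep(prof, each = nr), nr, nc), pixel_size_nm,
              name = sprintf("ridge_pair_h%.2f", h))
}

# round doubles to the nearest single-precision float
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

write_tmp_tiff <- function(m, pixel_size_nm = 10) {
  path <- tempfile(fileext = ".tif")
  write_reconstruction(recon_image(m, pixel_size_nm), path)
  path
}
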
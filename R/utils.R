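# Internal numeric helpers shared by the simulator and the samplers.

# run code under a private RNG stream, restoring global state afterwards
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# bilinear interpolation of img (nx x ny) at continuous pixel coordinates
# (x, y); pixel (i, j) has centre (i - 0.5, j - 0.5). Coordinates are clamped
# to the centre grid, so callers must keep sampling inside the image.
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- pmin(pmax(x - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y - 0.5, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), ny - 2); j0 <- pmax(j0, 0)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  v00 <- img[cbind(i0 + 1L, j0 + 1L)]
  v10 <- img[cbind(i0 + 2L, j0 + 1L)]
  v01 <- img[cbind(i0 + 1L, j0 + 2L)]
  v11 <- img[cbind(i0 + 2L, j0 + 2L)]
  v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
    v01 * (1 - tx) * ty + v11 * tx * ty
}

# scatter weights w at continuous pixel coordinates (x, y) onto a grid,
# bilinearly split over the four neighbouring pixels (adjoint of
# bilinear_sample; conserves sum(w) for points >= half a pixel inside).
deposit_points <- function(dim, x, y, w) {
  nx <- dim[1]; ny <- dim[2]
  fx <- pmin(pmax(x - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y - 0.5, 0), ny - 1)
  i0 <- pmax(pmin(floor(fx), nx - 2), 0)
  j0 <- pmax(pmin(floor(fy), ny - 2), 0)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  idx <- c((j0) * nx + i0 + 1L, (j0) * nx + i0 + 2L,
           (j0 + 1L) * nx + i0 + 1L, (j0 + 1L) * nx + i0 + 2L)
  ww <- c(w * (1 - tx) * (1 - ty), w * tx * (1 - ty),
          w * (1 - tx) * ty, w * tx * ty)
  acc <- rowsum(ww, idx)
  img <- matrix(0, nx, ny)
  img[as.integer(rownames(acc))] <- acc
  img
}

# Gaussian blur wrapper returning a plain matrix; sigma in pixels.
# Uses a circular boundary so total intensity inside the grid is conserved.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  out <- EBImage::gblur(img, sigma = sigma_px,
                        radius = 2 * ceiling(4 * sigma_px) + 1)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# population standard deviation (divides by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
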
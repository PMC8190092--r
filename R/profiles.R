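#' Sample fluorescence along the anchored cell outline
#'
#' Intensity is sampled at `n` equally spaced normalised arc positions
#' `k/n, k = 0..n-1` along the contour (the anchored start and fixed
#' counterclockwise direction make positions comparable across cells). The
#' value at each position is the mean of bilinearly interpolated intensities
#' along the local normal segment of half-width `band` pixels (`2*band + 1`
#' samples; `band = 0` reads the single subpixel point on the outline).
#'
#' @param image numeric matrix (one channel).
#' @param contour a `cell_contour` from [extract_anchored_contour()].
#' @param band integer normal half-width in pixels.
#' @param n number of arc samples.
#' @param channel tag stored with the profile (e.g. `"gfp"`, `"chl"`).
#' @return object of class `periphery_profile`: list with `position`
#'   (normalised arc, length `n`), `value`, `region` (NA until
#'   [partition_regions()]), `channel`, `band_px`, `n`.
#' @export
sample_periphery <- function(image, contour, band = 1, n = 360,
                             channel = "gfp") {
  stopifnot(inherits(contour, "cell_contour"), n >= 8, band >= 0)
  xy <- contour$xy_px
  # closed-polygon resampling at arc positions t * total
  xs <- c(xy[, 1], xy[1, 1]); ys <- c(xy[, 2], xy[1, 2])
  al <- c(contour$arclen_px, contour$total_px)
  tpos <- (seq_len(n) - 1) / n
  s <- tpos * contour$total_px
  px <- stats::approx(al, xs, xout = s, rule = 2)$y
  py <- stats::approx(al, ys, xout = s, rule = 2)$y
  # local tangent by central difference over the resampled closed curve
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  tx <- px[ip] - px[im]; ty <- py[ip] - py[im]
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- ty / tl; ny <- -tx / tl      # outward for a counterclockwise contour
  offs <- seq(-band, band)
  sx <- sweep(matrix(nx, n, length(offs)), 2, offs, `*`) + px
  sy <- sweep(matrix(ny, n, length(offs)), 2, offs, `*`) + py
  if (any(sx < 0.5 | sx > nrow(image) - 0.5 |
          sy < 0.5 | sy > ncol(image) - 0.5))
    stop("sampling band extends outside the image")
  vals <- matrix(bilinear_sample(image, as.vector(sx), as.vector(sy)),
                 n, length(offs))
  structure(list(position = tpos, value = rowMeans(vals),
                 region = rep(NA_character_, n), channel = channel,
                 band_px = band, n = n),
            class = "periphery_profile")
}

#' Label profile samples as sides and poles
#'
#' Maps each normalised arc position onto the straight-side / cap
#' decomposition of the fitted spherocylinder. From the anchor the labels
#' run: second half of L1, P1, L2, P2, first half of L1. In the sphere limit
#' `L = W` the sides vanish; the profile is then all caps and a warning is
#' raised.
#'
#' @param profile a `periphery_profile`.
#' @param geometry the cell's [rod_geometry()].
#' @return the profile with `region` filled in.
#' @export
partition_regions <- function(profile, geometry) {
  stopifnot(inherits(profile, "periphery_profile"))
  if (geometry$length_um == geometry$width_um)
    warning("degenerate geometry (L = W): no longitudinal sides, poles only")
  profile$region <- region_of_arc(geometry, profile$position)
  profile
}

#' Average periphery profiles across cells
#'
#' Pointwise arithmetic mean at matching normalised positions; no curve
#' registration is performed (cells are aligned purely by the anchored
#' start/direction convention).
#'
#' @param profiles list of `periphery_profile`s sharing `n` and `channel`.
#' @return object of class `mean_profile`: `position`, `mean` curve,
#'   `values` matrix (`n_cells x n`), `n_cells`, `channel`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "periphery_profile")))
  ns <- vapply(profiles, function(p) as.integer(p$n), 0L)
  chs <- vapply(profiles, function(p) p$channel, "")
  if (length(unique(ns)) != 1) stop("profiles differ in sample count")
  if (length(unique(chs)) != 1) stop("profiles differ in channel")
  V <- do.call(rbind, lapply(profiles, function(p) p$value))
  structure(list(position = profiles[[1]]$position, mean = colMeans(V),
                 values = V, n_cells = length(profiles),
                 channel = chs[1]),
            class = "mean_profile")
}
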
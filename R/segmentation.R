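#' Segment cells in an intensity image
#'
#' Otsu threshold (on the channel supplied, by default the Chl channel of a
#' fluorescence render), morphological closing, hole filling, connected
#' components and an area filter. For dark-object images (TEM polarity) set
#' `polarity = "dark"`.
#'
#' @param image numeric matrix.
#' @param pixel_size_nm pixel edge in nm (for the area filter).
#' @param min_area_um2 minimum object area in square micrometres.
#' @param polarity `"bright"` (objects above threshold) or `"dark"`.
#' @param close_radius_px radius of the closing brush in pixels.
#' @param smooth_sigma_px Gaussian pre-smoothing before thresholding
#'   (suppresses shot-noise outliers); 0 disables.
#' @param keep_border logical; keep masks touching the image border
#'   (default drops them).
#' @return list of `cell_mask` objects: each a list with logical matrix
#'   `mask` (full image size), integer `bbox` `(x0, x1, y0, y1)` (0-based,
#'   half-open), `area_px`, and `border` flag. Empty list on blank input.
#' @export
segment_cells <- function(image, pixel_size_nm = 30, min_area_um2 = 0.5,
                          polarity = c("bright", "dark"),
                          close_radius_px = 5, smooth_sigma_px = 1,
                          keep_border = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (smooth_sigma_px > 0) image <- gaussian_blur(image, smooth_sigma_px)
  rng <- range(image)
  if (diff(rng) == 0) return(list())
  norm <- (image - rng[1]) / diff(rng)
  if (polarity == "dark") norm <- 1 - norm
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > th
  # drop speckles before closing so noise cannot bridge objects
  bw <- EBImage::opening(bw, EBImage::makeBrush(3, shape = "box"))
  if (close_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * close_radius_px + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush)
  }
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  min_px <- min_area_um2 * 1e6 / pixel_size_nm^2
  out <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    m <- lab == id
    if (sum(m) < min_px) next
    ij <- which(m, arr.ind = TRUE)
    border <- any(ij[, 1] %in% c(1L, nrow(image))) ||
      any(ij[, 2] %in% c(1L, ncol(image)))
    if (border && !keep_border) next
    out[[length(out) + 1]] <- structure(
      list(mask = m,
           bbox = c(min(ij[, 1]) - 1L, max(ij[, 1]),
                    min(ij[, 2]) - 1L, max(ij[, 2])),
           area_px = sum(m), border = border),
      class = "cell_mask")
  }
  out
}

#' Fit the spherocylinder model to a cell mask
#'
#' Orientation from second-order image moments of the mask; length from the
#' extent of pixel centres along the major axis plus one pixel; width as the
#' area-preserving solution of `(L - W) W + pi (W/2)^2 = A`.
#'
#' @param mask a `cell_mask` from [segment_cells()] (or any logical matrix).
#' @param pixel_size_nm pixel edge in nm.
#' @return a [rod_geometry()] in micrometre units (image coordinate frame).
#'   If the mask touches the border a warning is raised, geometry is still
#'   returned.
#' @export
fit_rod <- function(mask, pixel_size_nm = 30) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  ij <- which(m, arr.ind = TRUE)
  if (nrow(ij) == 0) stop("empty mask")
  if (inherits(mask, "cell_mask") && isTRUE(mask$border))
    warning("mask touches the image border; geometry may be truncated")
  px_um <- pixel_size_nm / 1000
  x <- (ij[, 1] - 0.5) * px_um
  y <- (ij[, 2] - 0.5) * px_um
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  u <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  proj <- (x - cx) * u[1] + (y - cy) * u[2]
  L <- diff(range(proj)) + px_um
  A <- nrow(ij) * px_um^2
  # (L - W) W + pi W^2 / 4 = A  ->  (pi/4 - 1) W^2 + L W - A = 0
  a <- pi / 4 - 1
  disc <- L^2 + 4 * a * A
  W <- if (disc < 0) A / L else (-L + sqrt(disc)) / (2 * a)
  W <- min(max(W, px_um), L)
  rod_geometry(c(cx, cy), theta %% 180, L, W)
}

#' Extract the anchored, oriented subpixel cell outline
#'
#' Marching squares (via [grDevices::contourLines()]) at the 0.5 level of the
#' Gaussian-smoothed binary mask yields a subpixel closed polygon. The
#' polygon is oriented counterclockwise (positive signed area) and
#' re-indexed so vertex 1 is the point nearest the midpoint of side L1 of
#' the fitted geometry — the same convention fluorescence tracing uses:
#' start in the middle of a longitudinal side, always the same side,
#' always the same direction. The operation is idempotent: re-anchoring an
#' already anchored contour changes nothing.
#'
#' @param mask a `cell_mask` or logical matrix.
#' @param geometry a [rod_geometry()] for the same cell (pixel-frame
#'   micrometre units as returned by [fit_rod()]).
#' @param pixel_size_nm pixel edge in nm.
#' @param smooth_sigma_px Gaussian pre-smoothing of the mask in px.
#' @return object of class `cell_contour`: list with matrix `xy_px`
#'   (vertices, pixel units), `arclen_px` (cumulative arc length per vertex,
#'   starting at 0), `total_px`, `pixel_size_nm`, `geometry`.
#' @export
extract_anchored_contour <- function(mask, geometry, pixel_size_nm = 30,
                                     smooth_sigma_px = 1) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  z <- gaussian_blur(m * 1, smooth_sigma_px)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)) - 0.5,
                                y = seq_len(ncol(z)) - 0.5, z = z,
                                levels = 0.5)
  if (length(cl) == 0) stop("no 0.5-level contour found in mask")
  # keep the longest contour (the cell outline)
  lens <- vapply(cl, function(c) sum(sqrt(diff(c$x)^2 + diff(c$y)^2)), 0)
  cc <- cl[[which.max(lens)]]
  xy <- cbind(cc$x, cc$y)
  # drop duplicated closing vertex if present
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 4) stop("degenerate contour")
  if (contour_self_intersects(xy))
    stop("contour is not simple: outline self-intersects")
  # enforce counterclockwise orientation (positive signed area)
  sa <- signed_area(xy)
  if (sa < 0) xy <- xy[nrow(xy):1, , drop = FALSE]
  # anchor at the vertex nearest the midpoint of side L1
  anchor_um <- outline_point(geometry, 0)$xy
  anchor_px <- um_to_px(anchor_um, pixel_size_nm)
  d2 <- (xy[, 1] - anchor_px[1])^2 + (xy[, 2] - anchor_px[2])^2
  k <- which.min(d2)
  if (k > 1) xy <- xy[c(k:nrow(xy), 1:(k - 1)), , drop = FALSE]
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  close_seg <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
  arclen <- c(0, cumsum(seg))
  structure(list(xy_px = xy, arclen_px = arclen,
                 total_px = arclen[length(arclen)] + close_seg,
                 pixel_size_nm = pixel_size_nm, geometry = geometry),
            class = "cell_contour")
}

# twice the signed area of a closed polygon (positive = counterclockwise)
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) segment-crossing check on a decimated polygon; adequate for cell
# outlines (a few hundred vertices)
contour_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n > 400) { idx <- unique(round(seq(1, n, length.out = 400))); xy <- xy[idx, , drop = FALSE]; n <- nrow(xy) }
  p <- xy; q <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[js, 1], p[js, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[js, 1], q[js, 2])
    d3 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], p[i, 1], p[i, 2])
    d4 <- cross(p[js, 1], p[js, 2], q[js, 1], q[js, 2], q[i, 1], q[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Total contour length in micrometres
#' @param contour a `cell_contour`.
#' @return length in micrometres.
#' @export
contour_length_um <- function(contour) {
  contour$total_px * contour$pixel_size_nm / 1000
}
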
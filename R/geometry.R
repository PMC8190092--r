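#' Spherocylinder cell geometry
#'
#' A rod-shaped cyanobacterium projects to a spherocylinder: a rectangle of
#' length `L - W` capped by two semicircles of diameter `W`. All modules share
#' this model and its arc-length coordinate (see [outline_point()]).
#'
#' @param center numeric length-2, cell centroid in micrometres `(x, y)`.
#' @param orientation_deg angle of the long axis in degrees; normalised to
#'   `[0, 180)`.
#' @param length_um tip-to-tip extent `L` in micrometres.
#' @param width_um diameter `W` in micrometres; requires `L >= W > 0`.
#' @return An object of class `rod_geometry`.
#' @examples
#' g <- rod_geometry(c(2, 1), 0, length_um = 3, width_um = 1)
#' rod_perimeter(g) # 2*(L - W) + pi*W
#' @export
rod_geometry <- function(center = c(0, 0), orientation_deg = 0,
                         length_um = 3, width_um = 1) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)),
            is.finite(orientation_deg), is.finite(length_um),
            is.finite(width_um))
  if (!(length_um >= width_um && width_um > 0))
    stop("rod geometry requires L >= W > 0")
  structure(list(center = as.numeric(center),
                 orientation_deg = orientation_deg %% 180,
                 length_um = as.numeric(length_um),
                 width_um = as.numeric(width_um)),
            class = "rod_geometry")
}

#' @export
print.rod_geometry <- function(x, ...) {
  cat(sprintf(
    "rod_geometry: L = %.3f um, W = %.3f um, theta = %.1f deg, center = (%.2f, %.2f)\n",
    x$length_um, x$width_um, x$orientation_deg, x$center[1], x$center[2]))
  invisible(x)
}

#' Spherocylinder outline perimeter
#'
#' `2 * (L - W) + pi * W` micrometres.
#' @param geometry a [rod_geometry()].
#' @return perimeter in micrometres.
#' @export
rod_perimeter <- function(geometry) {
  2 * (geometry$length_um - geometry$width_um) + pi * geometry$width_um
}

#' Spherocylinder projected area
#'
#' `(L - W) * W + pi * (W/2)^2` square micrometres.
#' @inheritParams rod_perimeter
#' @return area in square micrometres.
#' @export
rod_area <- function(geometry) {
  L <- geometry$length_um; W <- geometry$width_um
  (L - W) * W + pi * (W / 2)^2
}

# rotation matrix for the cell frame -> world frame
rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Arc-length fractions of the four periphery regions
#'
#' The periphery is partitioned into the two longitudinal sides (L1, L2) and
#' the two polar caps (P1, P2). Fractions depend only on the aspect ratio:
#' each side spans `(L - W) / P` and each pole `(pi * W / 2) / P` of the
#' perimeter `P`.
#' @inheritParams rod_perimeter
#' @return named numeric vector with elements `L1`, `P1`, `L2`, `P2`
#'   (summing to 1).
#' @export
region_fractions <- function(geometry) {
  P <- rod_perimeter(geometry)
  side <- (geometry$length_um - geometry$width_um) / P
  pole <- (pi * geometry$width_um / 2) / P
  c(L1 = side, P1 = pole, L2 = side, P2 = pole)
}

#' Point on the anchored cell outline
#'
#' The outline is parametrised by normalised arc length `t` in `[0, 1)`,
#' anchored at the midpoint of longitudinal side L1 and traversed
#' counterclockwise (positive signed area in the `(x, y)` plane). Side L1 is
#' defined geometrically as the side with smaller cell-frame `y`. From the
#' anchor the traversal passes the second half of L1, pole P1, side L2,
#' pole P2 and the first half of L1.
#'
#' @inheritParams rod_perimeter
#' @param t numeric vector of normalised arc positions; taken modulo 1.
#' @return list with matrices `xy` (n x 2, micrometres), `normal` (n x 2 unit
#'   outward normals) and character vector `region`.
#' @export
outline_point <- function(geometry, t) {
  t <- t %% 1
  L <- geometry$length_um; W <- geometry$width_um
  R <- W / 2; a <- (L - W) / 2
  P <- rod_perimeter(geometry)
  s <- t * P
  x <- numeric(length(s)); y <- numeric(length(s))
  nx <- numeric(length(s)); ny <- numeric(length(s))
  region <- character(length(s))

  # segment boundaries in arc length
  b1 <- a                 # end of L1 second half
  b2 <- a + pi * R        # end of P1
  b3 <- b2 + 2 * a        # end of L2
  b4 <- b3 + pi * R       # end of P2 (remainder is L1 first half)

  i <- s < b1
  x[i] <- s[i]; y[i] <- -R; nx[i] <- 0; ny[i] <- -1; region[i] <- "L1"
  i <- s >= b1 & s < b2
  phi <- -pi / 2 + (s[i] - b1) / R
  x[i] <- a + R * cos(phi); y[i] <- R * sin(phi)
  nx[i] <- cos(phi); ny[i] <- sin(phi); region[i] <- "P1"
  i <- s >= b2 & s < b3
  x[i] <- a - (s[i] - b2); y[i] <- R; nx[i] <- 0; ny[i] <- 1; region[i] <- "L2"
  i <- s >= b3 & s < b4
  phi <- pi / 2 + (s[i] - b3) / R
  x[i] <- -a + R * cos(phi); y[i] <- R * sin(phi)
  nx[i] <- cos(phi); ny[i] <- sin(phi); region[i] <- "P2"
  i <- s >= b4
  x[i] <- -a + (s[i] - b4); y[i] <- -R; nx[i] <- 0; ny[i] <- -1; region[i] <- "L1"

  Rm <- rot2(geometry$orientation_deg)
  xy <- cbind(x, y) %*% t(Rm)
  xy[, 1] <- xy[, 1] + geometry$center[1]
  xy[, 2] <- xy[, 2] + geometry$center[2]
  nrm <- cbind(nx, ny) %*% t(Rm)
  colnames(xy) <- c("x", "y"); colnames(nrm) <- c("x", "y")
  list(xy = xy, normal = nrm, region = region)
}

#' Region label for arc positions
#'
#' @inheritParams outline_point
#' @return character vector of labels in `{"L1","P1","L2","P2"}`.
#' @export
region_of_arc <- function(geometry, t) {
  outline_point(geometry, t)$region
}

#' Inward-offset geometry (concentric shell outline)
#'
#' A parallel curve of the spherocylinder outline offset inward by `d` is the
#' outline of a spherocylinder with `L - 2d` and `W - 2d` at the same pose;
#' this is how concentric thylakoid shells are modelled.
#'
#' @inheritParams rod_perimeter
#' @param offset_um inward offset in micrometres; must satisfy
#'   `offset_um < W/2`.
#' @return a [rod_geometry()].
#' @export
shrink_geometry <- function(geometry, offset_um) {
  if (offset_um < 0 || offset_um >= geometry$width_um / 2)
    stop("shell offset must lie in [0, W/2)")
  rod_geometry(geometry$center, geometry$orientation_deg,
               geometry$length_um - 2 * offset_um,
               geometry$width_um - 2 * offset_um)
}

#' Rasterised ground-truth cell footprint
#'
#' Pixels whose centre lies within `W/2` of the cell's axis segment.
#' Pixel `(i, j)` covers `[(i-1), i] x [(j-1), j]` in pixel units with centre
#' at `(i - 0.5, j - 0.5)`; world coordinates are micrometres with origin at
#' the corner of pixel `(1, 1)`.
#'
#' @inheritParams rod_perimeter
#' @param dim integer length-2, image dimensions `(nx, ny)` in pixels.
#' @param pixel_size_nm pixel edge in nanometres.
#' @return logical matrix of dimension `dim`.
#' @export
footprint_mask <- function(geometry, dim, pixel_size_nm) {
  px_um <- pixel_size_nm / 1000
  cx <- (seq_len(dim[1]) - 0.5) * px_um
  cy <- (seq_len(dim[2]) - 0.5) * px_um
  u <- rot2(geometry$orientation_deg) %*% c(1, 0)
  a <- (geometry$length_um - geometry$width_um) / 2
  p1 <- geometry$center - a * as.numeric(u)
  p2 <- geometry$center + a * as.numeric(u)
  X <- matrix(cx, dim[1], dim[2])
  Y <- matrix(cy, dim[1], dim[2], byrow = TRUE)
  # distance from each pixel centre to the axis segment [p1, p2]
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    dist2 <- (X - p1[1])^2 + (Y - p1[2])^2
  } else {
    tt <- ((X - p1[1]) * dx + (Y - p1[2]) * dy) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dist2 <- (X - (p1[1] + tt * dx))^2 + (Y - (p1[2] + tt * dy))^2
  }
  dist2 <= (geometry$width_um / 2)^2
}
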
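# Forward rendering of scene specifications into images.

# pixel coordinates (continuous) of world points in micrometres
um_to_px <- function(xy_um, pixel_size_nm) xy_um * 1000 / pixel_size_nm

# required grid size for a scene (cell bbox + 3 sigma of PSF)
required_dim <- function(scene) {
  g <- scene$geometry; o <- scene$optics
  a <- (g$length_um - g$width_um) / 2; R <- g$width_um / 2
  thr <- g$orientation_deg * pi / 180
  need_nm <- 3 * o$psf_sigma_nm
  hx <- a * abs(cos(thr)) + R + need_nm / 1000
  hy <- a * abs(sin(thr)) + R + need_nm / 1000
  c(ceiling(2 * hx * 1000 / o$pixel_size_nm),
    ceiling(2 * hy * 1000 / o$pixel_size_nm))
}

check_grid <- function(scene) {
  if (any(scene$dim < required_dim(scene)))
    stop("pixel grid too small to contain the cell plus a 3*psf margin")
}

# world-space positions (um) of the scene's protein points
protein_positions <- function(scene) {
  if (nrow(scene$proteins) == 0)
    return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("x", "y"))))
  xy <- matrix(0, nrow(scene$proteins), 2)
  for (k in sort(unique(scene$proteins$shell))) {
    i <- scene$proteins$shell == k
    geom_k <- if (k == 0) scene$geometry
              else shrink_geometry(scene$geometry,
                                   scene$shells$offset_nm[k] / 1000)
    xy[i, ] <- outline_point(geom_k, scene$proteins$t[i])$xy
  }
  colnames(xy) <- c("x", "y")
  xy
}

# deposit a shell outline (or arc) as uniform line mass, density per px length
deposit_outline <- function(dim, geometry, pixel_size_nm, density,
                            arc_center = 0, arc_extent = 1, step_px = 0.25) {
  perim_px <- rod_perimeter(geometry) * 1000 / pixel_size_nm
  n <- max(8L, ceiling(perim_px * arc_extent / step_px))
  dt <- arc_extent / n
  tt <- (arc_center - arc_extent / 2) + (seq_len(n) - 0.5) * dt
  xy <- um_to_px(outline_point(geometry, tt)$xy, pixel_size_nm)
  deposit_points(dim, xy[, 1], xy[, 2], rep(density * dt * perim_px, n))
}

apply_noise <- function(img, optics, seed) {
  if (optics$poisson_gain == 0 && optics$read_sigma == 0) return(img)
  with_local_seed(seed, {
    if (optics$poisson_gain > 0) {
      lam <- pmax(img, 0) / optics$poisson_gain
      img <- matrix(stats::rpois(length(lam), lam) * optics$poisson_gain,
                    nrow(img), ncol(img))
    }
    if (optics$read_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, optics$read_sigma),
                          nrow(img), ncol(img))
    img
  })
}

#' Render the two-channel fluorescence image of a scene
#'
#' GFP channel: each protein point contributes a Gaussian kernel of its
#' amplitude (total intensity is conserved by the blur). Chl channel: the
#' thylakoid shells as uniform-intensity lines. Both are convolved with the
#' PSF, then background, Poisson and Gaussian read noise are applied in that
#' order; setting `noise = FALSE` (or zero gains in the optics) disables the
#' stochastic terms.
#'
#' @param scene a [make_scene()] result.
#' @param noise logical; `FALSE` renders the noise-free expectation
#'   (background still added).
#' @param chl_density Chl-channel line intensity in counts per pixel of arc
#'   length, before blur.
#' @return list of class `fluor_render`: matrices `gfp` and `chl`
#'   (`scene$dim`), logical ground-truth `footprint`, and `pixel_size_nm`.
#' @export
render_fluorescence <- function(scene, noise = TRUE, chl_density = 60) {
  stopifnot(inherits(scene, "scene_spec"))
  check_grid(scene)
  o <- scene$optics
  sig_px <- o$psf_sigma_nm / o$pixel_size_nm
  gfp <- matrix(0, scene$dim[1], scene$dim[2])
  if (nrow(scene$proteins) > 0) {
    xy <- um_to_px(protein_positions(scene), o$pixel_size_nm)
    gfp <- deposit_points(scene$dim, xy[, 1], xy[, 2],
                          scene$proteins$amplitude)
  }
  gfp <- gaussian_blur(gfp, sig_px)
  chl <- matrix(0, scene$dim[1], scene$dim[2])
  if (nrow(scene$shells) > 0) {
    for (k in seq_len(nrow(scene$shells))) {
      geom_k <- shrink_geometry(scene$geometry,
                                scene$shells$offset_nm[k] / 1000)
      chl <- chl + deposit_outline(scene$dim, geom_k, o$pixel_size_nm,
                                   chl_density,
                                   scene$shells$arc_center[k],
                                   scene$shells$arc_extent[k])
    }
  }
  chl <- gaussian_blur(chl, sig_px)
  gfp <- gfp + o$background
  chl <- chl + o$background
  if (noise) {
    gfp <- apply_noise(gfp, o, scene$seed + 1001L)
    chl <- apply_noise(chl, o, scene$seed + 1002L)
  }
  structure(list(gfp = gfp, chl = chl,
                 footprint = footprint_mask(scene$geometry, scene$dim,
                                            o$pixel_size_nm),
                 pixel_size_nm = o$pixel_size_nm),
            class = "fluor_render")
}

#' Render a thin-section (TEM-like) image of a scene
#'
#' Membranes appear as dark Gaussian-profile lines on a brighter cytoplasm
#' (heavy-metal stain polarity). The plasma membrane is always rendered; the
#' thylakoid shells follow the scene's shell set. The cytoplasm sits
#' `interior_drop` counts below the embedding background; membrane line mass
#' is blurred with the PSF combined with the membrane's own width and
#' subtracted. Poisson and read noise follow the scene optics.
#'
#' @param scene a [make_scene()] result (use [tem_optics()] in its params).
#' @param noise logical; `FALSE` gives the noise-free expectation.
#' @param membrane_sigma_nm Gaussian half-width of a membrane line in nm.
#' @param line_density membrane line mass in counts per pixel of arc length.
#' @param interior_drop counts by which the cytoplasm is darker than the
#'   exterior.
#' @return list of class `tem_render`: matrix `image`, logical ground-truth
#'   `footprint`, `pixel_size_nm`, and `layers` — the ground-truth signed
#'   mid-cell membrane positions (nm; negative = side L1) including the
#'   plasma membrane.
#' @export
render_tem <- function(scene, noise = TRUE, membrane_sigma_nm = 8,
                       line_density = 600, interior_drop = 40) {
  stopifnot(inherits(scene, "scene_spec"))
  check_grid(scene)
  o <- scene$optics
  px <- o$pixel_size_nm
  exterior <- o$background + interior_drop
  fp <- footprint_mask(scene$geometry, scene$dim, px)
  base <- matrix(exterior, scene$dim[1], scene$dim[2])
  base[fp] <- o$background
  base <- gaussian_blur(base, o$psf_sigma_nm / px)

  mass <- deposit_outline(scene$dim, scene$geometry, px, line_density)
  if (nrow(scene$shells) > 0) {
    for (k in seq_len(nrow(scene$shells))) {
      geom_k <- shrink_geometry(scene$geometry, scene$shells$offset_nm[k] / 1000)
      mass <- mass + deposit_outline(scene$dim, geom_k, px, line_density,
                                     scene$shells$arc_center[k],
                                     scene$shells$arc_extent[k])
    }
  }
  sig_eff <- sqrt(o$psf_sigma_nm^2 + membrane_sigma_nm^2) / px
  img <- pmax(base - gaussian_blur(mass, sig_eff), 1)
  if (noise) img <- apply_noise(img, o, scene$seed + 2001L)
  structure(list(image = img, footprint = fp, pixel_size_nm = px,
                 layers = scene_layer_positions(scene)),
            class = "tem_render")
}

#' Ground-truth membrane positions on the mid-cell transect
#'
#' Signed offsets (nm) from the cell axis of every membrane crossing the
#' perpendicular transect through the cell centre: negative = side L1,
#' positive = side L2. Includes the plasma membrane at `+/- W/2`; shells
#' appear on a side only when their arc covers that side's midpoint.
#'
#' @param scene a `scene_spec`.
#' @return data.frame with columns `position_nm`, `shell` (0 = plasma
#'   membrane), `side` (1 or 2).
#' @export
scene_layer_positions <- function(scene) {
  W_nm <- scene$geometry$width_um * 1000
  fr <- region_fractions(scene$geometry)
  t_mid2 <- fr[["L1"]] / 2 + fr[["P1"]] + fr[["L2"]] / 2
  pos <- data.frame(position_nm = c(-W_nm / 2, W_nm / 2),
                    shell = c(0L, 0L), side = c(1L, 2L))
  if (nrow(scene$shells) > 0) {
    cov1 <- shell_covers(scene$shells, 0)[, 1]
    cov2 <- shell_covers(scene$shells, t_mid2)[, 1]
    for (k in seq_len(nrow(scene$shells))) {
      r_nm <- W_nm / 2 - scene$shells$offset_nm[k]
      if (cov1[k]) pos <- rbind(pos, data.frame(position_nm = -r_nm,
                                                shell = k, side = 1L))
      if (cov2[k]) pos <- rbind(pos, data.frame(position_nm = r_nm,
                                                shell = k, side = 2L))
    }
  }
  pos[order(pos$position_nm), , drop = FALSE]
}
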
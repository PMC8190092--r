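#' Thylakoid shell set
#'
#' Concentric thylakoid membranes are modelled as inward-parallel outlines of
#' the plasma membrane. Each shell is an arc on its offset outline: a full
#' ring (`arc_extent = 1`) or a fragment (`arc_extent < 1`) centred at
#' normalised arc position `arc_center` of that outline (same anchoring
#' convention as [outline_point()]).
#'
#' @param offset_nm numeric, inward offsets from the plasma membrane in nm;
#'   strictly increasing.
#' @param arc_center numeric, arc centre per shell in `[0, 1)` (ignored for
#'   full rings; recycled).
#' @param arc_extent numeric in `(0, 1]`, arc fraction per shell (recycled);
#'   1 means a continuous ring.
#' @return data.frame of class `shell_set` with columns `offset_nm`,
#'   `arc_center`, `arc_extent`.
#' @export
shell_set <- function(offset_nm = numeric(), arc_center = 0, arc_extent = 1) {
  n <- length(offset_nm)
  arc_center <- rep_len(arc_center, n) %% 1
  arc_extent <- rep_len(arc_extent, n)
  if (n > 0) {
    if (any(diff(offset_nm) <= 0)) stop("shell offsets must be strictly increasing")
    if (any(offset_nm < 0)) stop("shell offsets must be non-negative")
    if (any(arc_extent <= 0 | arc_extent > 1)) stop("arc extents must be in (0, 1]")
  }
  structure(data.frame(offset_nm = as.numeric(offset_nm),
                       arc_center = arc_center, arc_extent = arc_extent),
            class = c("shell_set", "data.frame"))
}

# does shell arc cover normalised arc position t (circular distance)?
shell_covers <- function(shells, t) {
  if (nrow(shells) == 0) return(matrix(FALSE, 0, length(t)))
  out <- matrix(FALSE, nrow(shells), length(t))
  for (k in seq_len(nrow(shells))) {
    if (shells$arc_extent[k] >= 1) { out[k, ] <- TRUE; next }
    d <- abs((t - shells$arc_center[k]) %% 1)
    d <- pmin(d, 1 - d)
    out[k, ] <- d <= shells$arc_extent[k] / 2
  }
  out
}

#' Condition presets for the shell architecture
#'
#' Shell layouts emulating the thylakoid ultrastructure of *Synechococcus*
#' under the growth-light (GL), high-light (HL) and low-light recovery
#' (LL day 1..5) conditions: GL cells carry 3 concentric layers at 78.4 nm
#' spacing; HL cells one continuous layer plus a membrane fragment close to
#' the plasma membrane on one longitudinal side, the two 109.2 nm apart;
#' LL presets interpolate the regrowth (an extra layer first appears on the
#' fragment side, spacing relaxing back towards the GL value).
#'
#' @param preset one of `"GL"`, `"HL"`, `"LL1"`..`"LL5"`.
#' @return a [shell_set()].
#' @export
preset_shells <- function(preset) {
  switch(preset,
    GL  = shell_set(78.4 * (1:3)),
    HL  = shell_set(c(60, 169.2), arc_center = c(0, 0), arc_extent = c(0.22, 1)),
    LL1 = shell_set(c(60, 170.6, 281.2), arc_center = 0,
                    arc_extent = c(0.25, 0.45, 1)),
    LL2 = shell_set(c(95, 190, 285), arc_center = 0, arc_extent = c(1, 1, 0.5)),
    LL3 = shell_set(85 * (1:3)),
    LL4 = shell_set(80 * (1:3)),
    LL5 = shell_set(78.4 * (1:3)),
    stop("unknown preset: ", preset)
  )
}

#' Protein point-distribution parameters
#'
#' Protein positions along the periphery are drawn from a density on the
#' normalised arc: a mixture of `n_clusters` wrapped (von Mises) components of
#' concentration `kappa` (0 reduces to uniform), multiplied by per-region
#' weights: `side_asymmetry` on side L1, 1 on side L2, and
#' `polar_enrichment` times the mean side weight on the polar caps.
#'
#' @param n_points number of protein points (>= 0).
#' @param kappa clustering concentration (dimensionless, >= 0; 0 = uniform).
#' @param n_clusters number of cluster centres (>= 1 when `kappa > 0`).
#' @param side_asymmetry density ratio side1 / side2 (>= 0).
#' @param polar_enrichment relative density multiplier on the caps (>= 0).
#' @param amplitude integrated intensity per protein point in counts
#'   (a GFP spot's photon budget; >= 0).
#' @return list of class `protein_distribution`.
#' @export
protein_distribution <- function(n_points = 2000, kappa = 0, n_clusters = 4,
                                 side_asymmetry = 1, polar_enrichment = 1,
                                 amplitude = 500) {
  stopifnot(n_points >= 0, kappa >= 0, n_clusters >= 1,
            side_asymmetry >= 0, polar_enrichment >= 0, amplitude >= 0)
  structure(list(n_points = as.integer(n_points), kappa = kappa,
                 n_clusters = as.integer(n_clusters),
                 side_asymmetry = side_asymmetry,
                 polar_enrichment = polar_enrichment,
                 amplitude = amplitude),
            class = "protein_distribution")
}

#' Optics and noise parameters
#'
#' @param pixel_size_nm pixel edge in nanometres (> 0). Defaults: 30 nm/px
#'   for fluorescence, 5 nm/px via [tem_optics()].
#' @param psf_sigma_nm Gaussian point-spread sigma in nm (>= 0).
#' @param background constant offset in counts, added after blur.
#' @param poisson_gain counts per photon for shot noise; 0 disables.
#' @param read_sigma Gaussian read-noise SD in counts; 0 disables.
#' @param margin_nm empty margin around the cell; defaults to
#'   `3 * psf_sigma_nm + 300`.
#' @return list of class `optics_params`.
#' @export
optics_params <- function(pixel_size_nm = 30, psf_sigma_nm = 100,
                          background = 10, poisson_gain = 1, read_sigma = 2,
                          margin_nm = NULL) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm >= 0, read_sigma >= 0,
            poisson_gain >= 0)
  if (is.null(margin_nm)) margin_nm <- 3 * psf_sigma_nm + 300
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 background = background, poisson_gain = poisson_gain,
                 read_sigma = read_sigma, margin_nm = margin_nm),
            class = "optics_params")
}

#' @rdname optics_params
#' @export
tem_optics <- function(pixel_size_nm = 5, psf_sigma_nm = 10,
                       background = 180, poisson_gain = 1, read_sigma = 3,
                       margin_nm = 150) {
  optics_params(pixel_size_nm, psf_sigma_nm, background, poisson_gain,
                read_sigma, margin_nm)
}

#' Simulation parameters for one cell scene
#'
#' @param preset condition label (`"GL"`, `"HL"`, `"LL1"`..`"LL5"`,
#'   `"custom"`). For named presets the shell layout defaults to
#'   [preset_shells()].
#' @param shells a [shell_set()]; overrides the preset layout.
#' @param length_um,width_um mean cell dimensions (micrometres).
#' @param length_sd_um,width_sd_um cell-to-cell SD of the dimensions.
#' @param orientation_deg cell orientation; `NA` draws uniformly in
#'   `[0, 180)`.
#' @param distribution a [protein_distribution()].
#' @param optics an [optics_params()].
#' @return list of class `scene_params`.
#' @export
scene_params <- function(preset = "GL", shells = NULL,
                         length_um = 3, width_um = 1,
                         length_sd_um = 0.15, width_sd_um = 0.04,
                         orientation_deg = NA,
                         distribution = protein_distribution(),
                         optics = optics_params()) {
  known <- c("GL", "HL", paste0("LL", 1:5), "custom")
  if (!preset %in% known) stop("unknown preset: ", preset)
  if (is.null(shells)) {
    shells <- if (preset == "custom") shell_set(78.4 * (1:3))
              else preset_shells(preset)
  }
  structure(list(preset = preset, shells = shells,
                 length_um = length_um, width_um = width_um,
                 length_sd_um = length_sd_um, width_sd_um = width_sd_um,
                 orientation_deg = orientation_deg,
                 distribution = distribution, optics = optics),
            class = "scene_params")
}

# arc density on a fine grid: von Mises cluster mixture times region weights.
# Side weights are `side_asymmetry` on L1 and 1 on L2; across each cap the
# weight interpolates linearly between the adjoining side levels (density is
# continuous around the outline) and is multiplied by `polar_enrichment`.
arc_density_grid <- function(geometry, dist, mu, M = 4096L) {
  tg <- (seq_len(M) - 0.5) / M
  base <- if (dist$kappa == 0 || length(mu) == 0) rep(1, M) else {
    rowMeans(exp(dist$kappa * cos(2 * pi * outer(tg, mu, `-`))))
  }
  a <- dist$side_asymmetry
  fr <- region_fractions(geometry)
  b1 <- fr[["L1"]] / 2            # end of L1 second half
  b2 <- b1 + fr[["P1"]]
  b3 <- b2 + fr[["L2"]]
  b4 <- b3 + fr[["P2"]]
  w <- rep(a, M)                  # L1 (both halves)
  i <- tg >= b2 & tg < b3
  w[i] <- 1                       # L2
  i <- tg >= b1 & tg < b2         # P1: L1 -> L2
  u <- (tg[i] - b1) / fr[["P1"]]
  w[i] <- dist$polar_enrichment * (a + (1 - a) * u)
  i <- tg >= b3 & tg < b4         # P2: L2 -> L1
  u <- (tg[i] - b3) / fr[["P2"]]
  w[i] <- dist$polar_enrichment * (1 + (a - 1) * u)
  list(t = tg, density = base * w)
}

#' Generate a fully specified synthetic cell scene
#'
#' Draws the cell geometry, the cluster centres and the protein points from a
#' single seeded stream, so identical `(params, seed)` give a bitwise
#' identical scene. The scene records complete ground truth (geometry, shell
#' layout, every protein point with its arc position, shell and side) for use
#' as an oracle by the analysis modules.
#'
#' @param params a [scene_params()].
#' @param seed integer seed for this scene's private RNG stream.
#' @return object of class `scene_spec`: list with elements `geometry`
#'   ([rod_geometry()]), `shells`, `proteins` (data.frame `t`, `shell`,
#'   `amplitude`, `region`), `distribution`, `optics`, `dim` (image size in
#'   px), `preset`, `seed`.
#' @export
make_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  with_local_seed(seed, {
    L <- max(params$width_um * 1.001,
             stats::rnorm(1, params$length_um, params$length_sd_um))
    W <- max(0.2, stats::rnorm(1, params$width_um, params$width_sd_um))
    if (L < W) L <- W
    th <- if (is.na(params$orientation_deg)) stats::runif(1, 0, 180)
          else params$orientation_deg
    px <- params$optics$pixel_size_nm / 1000
    margin <- params$optics$margin_nm / 1000
    a <- (L - W) / 2; R <- W / 2
    thr <- th * pi / 180
    hx <- a * abs(cos(thr)) + R + margin
    hy <- a * abs(sin(thr)) + R + margin
    dim <- c(2L * as.integer(ceiling(hx / px)), 2L * as.integer(ceiling(hy / px)))
    geometry <- rod_geometry(center = c(dim[1] * px / 2, dim[2] * px / 2),
                             orientation_deg = th, length_um = L, width_um = W)
    shells <- params$shells
    if (nrow(shells) > 0 && any(shells$offset_nm >= W * 500))
      stop("shell offsets must be smaller than W/2")

    dist <- params$distribution
    n <- dist$n_points
    mu <- if (dist$kappa > 0) stats::runif(dist$n_clusters) else numeric()
    if (n > 0) {
      dg <- arc_density_grid(geometry, dist, mu)
      M <- length(dg$t)
      bin <- sample.int(M, n, replace = TRUE, prob = dg$density)
      t <- (bin - 1 + stats::runif(n)) / M
      cov <- shell_covers(shells, t)
      shell_idx <- integer(n)
      for (i in seq_len(n)) {
        ok <- which(cov[, i])
        shell_idx[i] <- if (length(ok) == 0) 0L
                        else ok[sample.int(length(ok), 1)]
      }
      proteins <- data.frame(t = t, shell = shell_idx,
                             amplitude = dist$amplitude,
                             region = region_of_arc(geometry, t),
                             stringsAsFactors = FALSE)
    } else {
      proteins <- data.frame(t = numeric(), shell = integer(),
                             amplitude = numeric(), region = character(),
                             stringsAsFactors = FALSE)
    }
    structure(list(geometry = geometry, shells = shells, proteins = proteins,
                   distribution = dist, optics = params$optics,
                   dim = dim, preset = params$preset,
                   cluster_centers = mu, seed = as.integer(seed)),
              class = "scene_spec")
  })
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec [%s] seed %d: %d shells, %d proteins, %dx%d px @ %g nm/px\n",
              x$preset, x$seed, nrow(x$shells), nrow(x$proteins),
              x$dim[1], x$dim[2], x$optics$pixel_size_nm))
  invisible(x)
}

#' Serialise / restore a scene specification
#'
#' Full-precision JSON round trip; `scene_from_json(scene_to_json(s))` is
#' identical to `s`. The sidecar schema is versioned.
#' @param scene a `scene_spec`.
#' @param path optional file path; when given, writes/reads the file.
#' @return `scene_to_json`: a JSON string (invisibly when `path` given);
#'   `scene_from_json`: a `scene_spec`.
#' @export
scene_to_json <- function(scene, path = NULL) {
  x <- list(schema = "thylaquant-scene/1",
            geometry = unclass(scene$geometry),
            shells = as.data.frame(scene$shells),
            proteins = scene$proteins,
            distribution = unclass(scene$distribution),
            optics = unclass(scene$optics),
            dim = scene$dim, preset = scene$preset,
            cluster_centers = scene$cluster_centers, seed = scene$seed)
  js <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname scene_to_json
#' @param json JSON string (ignored when `path` given).
#' @export
scene_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "")
  x <- jsonlite::fromJSON(json)
  if (!identical(x$schema, "thylaquant-scene/1"))
    stop("unrecognised scene schema")
  geometry <- rod_geometry(x$geometry$center, x$geometry$orientation_deg,
                           x$geometry$length_um, x$geometry$width_um)
  shells <- if (length(x$shells) == 0 || nrow(as.data.frame(x$shells)) == 0)
    shell_set() else shell_set(x$shells$offset_nm, x$shells$arc_center,
                               x$shells$arc_extent)
  pr <- as.data.frame(x$proteins)
  if (nrow(pr) == 0)
    pr <- data.frame(t = numeric(), shell = integer(), amplitude = numeric(),
                     region = character(), stringsAsFactors = FALSE)
  pr$shell <- as.integer(pr$shell)
  structure(list(geometry = geometry, shells = shells, proteins = pr,
                 distribution = do.call(protein_distribution, x$distribution),
                 optics = do.call(optics_params, x$optics),
                 dim = as.integer(x$dim), preset = x$preset,
                 cluster_centers = as.numeric(x$cluster_centers),
                 seed = as.integer(x$seed)),
            class = "scene_spec")
}
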
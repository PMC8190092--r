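#' Full TEM analysis of a single image
#'
#' Segment (dark polarity) -> fit the spherocylinder -> mid-cell transect ->
#' layer peaks -> per-side layer counts and inter-layer distances. The
#' largest segmented cell is analysed.
#'
#' @param image numeric matrix (TEM-like, membranes dark).
#' @param pixel_size_nm pixel edge in nm.
#' @param avg_width transect averaging width in px.
#' @param prominence_frac,min_separation_nm passed to
#'   [detect_layer_peaks()].
#' @param keep_border keep border-touching cells.
#' @return list: `geometry`, `transect`, `peaks`, `counts`
#'   ([layer_counts()]), `distances_nm` ([layer_distances()]). `NULL` when
#'   no cell is found.
#' @export
analyze_tem_image <- function(image, pixel_size_nm = 5, avg_width = 20,
                              prominence_frac = 0.2, min_separation_nm = 20,
                              keep_border = FALSE) {
  masks <- segment_cells(image, pixel_size_nm = pixel_size_nm,
                         polarity = "dark", keep_border = keep_border)
  if (length(masks) == 0) return(NULL)
  m <- masks[[which.max(vapply(masks, function(x) x$area_px, 0))]]
  geometry <- fit_rod(m, pixel_size_nm)
  tr <- midcell_transect(image, geometry, pixel_size_nm,
                         avg_width = avg_width)
  pk <- detect_layer_peaks(tr, prominence_frac = prominence_frac,
                           min_separation_nm = min_separation_nm)
  list(geometry = geometry, transect = tr, peaks = pk,
       counts = suppressWarnings(layer_counts(pk, geometry)),
       distances_nm = layer_distances(pk, geometry))
}

#' Simulated inter-layer spacing study
#'
#' Renders `n_cells` TEM-like cells per group (each group a concentric
#' shell layout with the given spacing), runs the full analysis pipeline on
#' every image, and pools the recovered inter-layer distances per group.
#'
#' @param spacings named numeric vector of shell spacings in nm, e.g.
#'   `c(GL = 78.4, HL = 109.2)`.
#' @param n_cells cells per group.
#' @param n_layers concentric layers per cell (offsets `s, 2s, ..`).
#' @param seed base seed; cell `i` of group `g` uses
#'   `seed + 1000 * g + i`.
#' @param noise logical, render with Poisson/read noise.
#' @return named list of numeric vectors (recovered distances, nm) ready
#'   for [spacing_summary()].
#' @export
simulate_spacing_study <- function(spacings = c(GL = 78.4, HL = 109.2),
                                   n_cells = 50, n_layers = 3, seed = 1,
                                   noise = TRUE) {
  stopifnot(!is.null(names(spacings)))
  out <- stats::setNames(vector("list", length(spacings)), names(spacings))
  for (g in seq_along(spacings)) {
    s <- spacings[g]
    dist_g <- numeric()
    for (i in seq_len(n_cells)) {
      sp <- scene_params(preset = "custom",
                         shells = shell_set(s * seq_len(n_layers)),
                         distribution = protein_distribution(n_points = 0),
                         optics = tem_optics())
      scene <- make_scene(sp, seed = seed + 1000 * g + i)
      img <- render_tem(scene, noise = noise)$image
      res <- analyze_tem_image(img, scene$optics$pixel_size_nm)
      if (!is.null(res)) dist_g <- c(dist_g, res$distances_nm)
    }
    out[[g]] <- dist_g
  }
  out
}

#' Periphery profile of one simulated cell
#'
#' Renders the two-channel fluorescence image, segments on the Chl channel,
#' fits the rod, extracts the anchored contour and samples the requested
#' channel, returning the region-labelled profile plus intermediates.
#'
#' @param scene a [make_scene()] result.
#' @param channel `"gfp"` or `"chl"`.
#' @param noise render with noise.
#' @param band,n passed to [sample_periphery()].
#' @return list: `profile` (labelled `periphery_profile`), `geometry`,
#'   `contour`, `mask`, `render`; `NULL` if segmentation found no cell.
#' @export
profile_scene <- function(scene, channel = c("gfp", "chl"), noise = TRUE,
                          band = 1, n = 360) {
  channel <- match.arg(channel)
  rnd <- render_fluorescence(scene, noise = noise)
  masks <- segment_cells(rnd$chl, pixel_size_nm = rnd$pixel_size_nm)
  if (length(masks) == 0) return(NULL)
  m <- masks[[which.max(vapply(masks, function(x) x$area_px, 0))]]
  geometry <- fit_rod(m, rnd$pixel_size_nm)
  contour <- extract_anchored_contour(m, geometry, rnd$pixel_size_nm)
  prof <- sample_periphery(rnd[[channel]], contour, band = band, n = n,
                           channel = channel)
  prof <- partition_regions(prof, geometry)
  list(profile = prof, geometry = geometry, contour = contour,
       mask = m, render = rnd)
}

#' Simulated periphery-statistics study
#'
#' Generates `n_cells` scenes from shared parameters (fresh seeds), profiles
#' each on the GFP channel and returns the per-cell patchiness and
#' side-asymmetry values together with the profiles.
#'
#' @param params a [scene_params()].
#' @param n_cells number of cells.
#' @param seed base seed; cell `i` uses `seed + i`.
#' @param noise render with noise.
#' @param band,n passed to [sample_periphery()].
#' @return list: data.frame `stats` (`cell`, `patchiness`, `asymmetry`,
#'   `brighter_side`), list `profiles`, and `mean_profile`
#'   ([average_profiles()]).
#' @export
simulate_periphery_study <- function(params, n_cells = 30, seed = 1,
                                     noise = TRUE, band = 1, n = 360) {
  profiles <- list()
  rows <- list()
  for (i in seq_len(n_cells)) {
    scene <- make_scene(params, seed = seed + i)
    res <- profile_scene(scene, "gfp", noise = noise, band = band, n = n)
    if (is.null(res)) next
    pv <- patchiness(res$profile)
    av <- side_asymmetry(res$profile)
    profiles[[length(profiles) + 1]] <- res$profile
    rows[[length(rows) + 1]] <- data.frame(
      cell = i, patchiness = pv$value, asymmetry = av$value,
      brighter_side = av$brighter_side, stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, rows), profiles = profiles,
       mean_profile = if (length(profiles) > 0) average_profiles(profiles)
                      else NULL)
}
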
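# Shared fixture builders. Everything is generated in code at test time.

# a fully deterministic hand-built scene (no RNG): explicit proteins/shells
hand_scene <- function(proteins = data.frame(t = numeric(), shell = integer(),
                                             amplitude = numeric(),
                                             region = character()),
                       shells = shell_set(),
                       length_um = 3, width_um = 1, orientation_deg = 0,
                       optics = optics_params(poisson_gain = 0, read_sigma = 0,
                                              background = 0)) {
  px <- optics$pixel_size_nm / 1000
  margin <- optics$margin_nm / 1000
  a <- (length_um - width_um) / 2; R <- width_um / 2
  thr <- orientation_deg * pi / 180
  hx <- a * abs(cos(thr)) + R + margin
  hy <- a * abs(sin(thr)) + R + margin
  dim <- c(2L * as.integer(ceiling(hx / px)), 2L * as.integer(ceiling(hy / px)))
  geometry <- rod_geometry(c(dim[1] * px / 2, dim[2] * px / 2),
                           orientation_deg, length_um, width_um)
  if (nrow(proteins) > 0 && is.null(proteins$region))
    proteins$region <- region_of_arc(geometry, proteins$t)
  structure(list(geometry = geometry, shells = shells, proteins = proteins,
                 distribution = protein_distribution(n_points = nrow(proteins)),
                 optics = optics, dim = dim, preset = "custom",
                 cluster_centers = numeric(), seed = 0L),
            class = "scene_spec")
}

# periphery profile built directly from values (for the statistics module)
hand_profile <- function(value, region = NULL, channel = "gfp") {
  n <- length(value)
  if (is.null(region)) region <- rep(NA_character_, n)
  structure(list(position = (seq_len(n) - 1) / n, value = value,
                 region = region, channel = channel, band_px = 1, n = n),
            class = "periphery_profile")
}

# transect profile from raw samples (positions in nm)
hand_transect <- function(intensity, pixel_size_nm = 5,
                          position_nm = NULL,
                          geometry = rod_geometry(c(0, 0), 0, 3, 1)) {
  if (is.null(position_nm))
    position_nm <- (seq_along(intensity) - 1) * pixel_size_nm
  structure(list(position_nm = position_nm, intensity = intensity,
                 geometry = geometry, pixel_size_nm = pixel_size_nm),
            class = "transect_profile")
}

# pooled two-sample t statistic from the definitional formula (oracle)
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
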
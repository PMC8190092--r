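#' Mid-cell intensity transect
#'
#' Samples intensity along the line through the cell centroid perpendicular
#' to the major axis, averaged over `avg_width` parallel lines one pixel
#' apart (membranes are locally parallel there, so averaging along the axis
#' suppresses noise without blurring the layer structure). Positions are in
#' nanometres, signed: negative = side L1, positive = side L2, origin on
#' the cell axis.
#'
#' @param image numeric matrix.
#' @param geometry the cell's [rod_geometry()] (pixel-frame micrometres).
#' @param pixel_size_nm pixel edge in nm.
#' @param avg_width number of parallel lines averaged.
#' @param margin_nm extension of the transect beyond `W/2` on each side.
#' @return object of class `transect_profile`: `position_nm` (strictly
#'   increasing, symmetric about 0), `intensity`, `geometry`,
#'   `pixel_size_nm`.
#' @export
midcell_transect <- function(image, geometry, pixel_size_nm = 5,
                             avg_width = 20, margin_nm = 100) {
  stopifnot(is.matrix(image), inherits(geometry, "rod_geometry"))
  px <- pixel_size_nm
  half_nm <- geometry$width_um * 500 + margin_nm
  m <- floor(half_nm / px)
  pos_nm <- seq(-m, m) * px
  th <- geometry$orientation_deg * pi / 180
  u <- c(cos(th), sin(th))          # major axis
  v <- c(-sin(th), cos(th))         # transect direction (+ = side L2)
  c_px <- um_to_px(geometry$center, px)
  offs <- (seq_len(avg_width) - (avg_width + 1) / 2)
  P <- pos_nm / px
  X <- outer(P, offs, function(p, o) c_px[1] + p * v[1] + o * u[1])
  Y <- outer(P, offs, function(p, o) c_px[2] + p * v[2] + o * u[2])
  if (any(X < 0.5 | X > nrow(image) - 0.5 | Y < 0.5 | Y > ncol(image) - 0.5))
    stop("transect exits the image")
  vals <- matrix(bilinear_sample(image, as.vector(X), as.vector(Y)),
                 length(P), avg_width)
  structure(list(position_nm = pos_nm, intensity = rowMeans(vals),
                 geometry = geometry, pixel_size_nm = px),
            class = "transect_profile")
}

# topographic prominence of local maxima of z (scipy-style definition)
peak_prominences <- function(z, peaks) {
  vapply(peaks, function(i) {
    # walk left to the previous higher point, tracking the lowest saddle
    lo_l <- z[i]
    j <- i - 1
    while (j >= 1 && z[j] <= z[i]) { lo_l <- min(lo_l, z[j]); j <- j - 1 }
    lo_r <- z[i]
    j <- i + 1
    while (j <= length(z) && z[j] <= z[i]) { lo_r <- min(lo_r, z[j]); j <- j + 1 }
    z[i] - max(lo_l, lo_r)
  }, 0)
}

#' Detect membrane layers as intensity minima of a transect
#'
#' Membranes are stained dark, so layers are local minima of the transect
#' (set `polarity = "bright"` for inverted contrast). Minima are kept if
#' their topographic prominence reaches `prominence_frac` of the transect's
#' dynamic range and enforced to be at least `min_separation_nm` apart
#' (greedy, most prominent first). Positions are refined to subpixel
#' precision by a 3-point parabolic fit through the minimum and its
#' neighbours. A light Gaussian pre-smoothing (`smooth_px`) stabilises the
#' parabolic step against pixel noise.
#'
#' @param transect a `transect_profile`.
#' @param prominence_frac minimum prominence as a fraction of the dynamic
#'   range.
#' @param min_separation_nm minimum distance between accepted layers.
#' @param polarity `"dark"` (minima, default) or `"bright"` (maxima).
#' @param smooth_px Gaussian pre-smoothing sigma in samples (0 disables).
#' @param refine logical; disable for integer-sample positions.
#' @return data.frame of class `layer_peaks`: `position_nm` (sorted),
#'   `prominence`, `side` (1 = negative positions, 2 = positive).
#' @export
detect_layer_peaks <- function(transect, prominence_frac = 0.2,
                               min_separation_nm = 20,
                               polarity = c("dark", "bright"),
                               smooth_px = 1, refine = TRUE) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(transect, "transect_profile"))
  y <- transect$intensity
  if (length(y) < 5) stop("transect must have at least 5 samples")
  pos <- transect$position_nm
  px <- transect$pixel_size_nm
  if (smooth_px > 0) {
    r <- ceiling(3 * smooth_px)
    k <- stats::dnorm(seq(-r, r), sd = smooth_px); k <- k / sum(k)
    y <- as.numeric(stats::filter(c(rep(y[1], r), y, rep(y[length(y)], r)),
                                  k, sides = 2))[(r + 1):(r + length(pos))]
  }
  z <- if (polarity == "dark") -y else y
  n <- length(z)
  cand <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  empty <- structure(data.frame(position_nm = numeric(),
                                prominence = numeric(), side = integer()),
                     class = c("layer_peaks", "data.frame"))
  if (length(cand) == 0) return(empty)
  prom <- peak_prominences(z, cand)
  thr <- prominence_frac * diff(range(transect$intensity))
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  # greedy min-separation filter, most prominent first
  ord <- order(prom, decreasing = TRUE)
  sel <- integer()
  for (i in ord) {
    if (all(abs(pos[cand[i]] - pos[cand[sel]]) >= min_separation_nm) ||
        length(sel) == 0) sel <- c(sel, i)
  }
  cand <- cand[sort(sel)]; prom <- prom[sort(sel)]
  p_nm <- pos[cand]
  if (refine) {
    for (k2 in seq_along(cand)) {
      i <- cand[k2]
      if (i > 1 && i < n) {
        denom <- z[i - 1] - 2 * z[i] + z[i + 1]
        if (denom < 0) {
          delta <- 0.5 * (z[i - 1] - z[i + 1]) / denom
          p_nm[k2] <- pos[i] + delta * px
        }
      }
    }
  }
  ord2 <- order(p_nm)
  structure(data.frame(position_nm = p_nm[ord2], prominence = prom[ord2],
                       side = ifelse(p_nm[ord2] < 0, 1L, 2L)),
            class = c("layer_peaks", "data.frame"))
}

#' Thylakoid layer counts per longitudinal side
#'
#' Removes the plasma-membrane peak on each side — the outermost detected
#' layer within `pm_tol_nm` of `W/2` — and counts the remaining (thylakoid)
#' layers by side. A missing plasma-membrane peak is flagged but counting
#' proceeds.
#'
#' @param peaks a `layer_peaks` data.frame.
#' @param geometry the cell's [rod_geometry()].
#' @param pm_tol_nm tolerance for identifying the plasma membrane.
#' @return list of class `layer_counts`: `side1`, `side2` (thylakoid layer
#'   counts), `pm_found` (logical length 2), `thylakoids` (the peaks with
#'   the plasma membrane removed).
#' @export
layer_counts <- function(peaks, geometry, pm_tol_nm = 40) {
  stopifnot(inherits(peaks, "layer_peaks"))
  half_nm <- geometry$width_um * 500
  pm_found <- c(FALSE, FALSE)
  drop <- logical(nrow(peaks))
  for (s in 1:2) {
    i <- which(peaks$side == s)
    if (length(i) == 0) next
    outer_i <- i[which.max(abs(peaks$position_nm[i]))]
    if (abs(abs(peaks$position_nm[outer_i]) - half_nm) <= pm_tol_nm) {
      pm_found[s] <- TRUE
      drop[outer_i] <- TRUE
    }
  }
  if (!all(pm_found))
    warning("plasma-membrane peak not found on side(s): ",
            paste(which(!pm_found), collapse = ", "))
  thy <- peaks[!drop, , drop = FALSE]
  structure(list(side1 = sum(thy$side == 1), side2 = sum(thy$side == 2),
                 pm_found = pm_found, thylakoids = thy),
            class = "layer_counts")
}

#' Inter-layer distances on each side
#'
#' Distances between adjacent thylakoid layers on the same side (plasma
#' membrane excluded via [layer_counts()]).
#'
#' @inheritParams layer_counts
#' @return numeric vector of distances in nm (possibly empty).
#' @export
layer_distances <- function(peaks, geometry, pm_tol_nm = 40) {
  lc <- suppressWarnings(layer_counts(peaks, geometry, pm_tol_nm))
  out <- numeric()
  for (s in 1:2) {
    p <- sort(lc$thylakoids$position_nm[lc$thylakoids$side == s])
    if (length(p) >= 2) out <- c(out, diff(p))
  }
  out
}

#' Group summary of inter-layer spacings
#'
#' Per-group mean, sample SD and n; percent change of each group mean
#' relative to a reference group, `100 * (mean - mean_ref) / mean_ref`; and
#' a two-sided two-sample t test of each group against the reference
#' ([compare_groups()]).
#'
#' @param groups named list of numeric vectors of inter-layer distances (nm).
#' @param reference name of the reference group.
#' @param welch logical, passed to [compare_groups()].
#' @return list of class `spacing_summary`: data.frame `table`
#'   (`group`, `mean_nm`, `sd_nm`, `n`, `percent_change`, `t`, `df`, `p`)
#'   and `reference`.
#' @export
spacing_summary <- function(groups, reference, welch = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  if (!reference %in% names(groups))
    stop("unknown reference group: ", reference)
  if (any(vapply(groups, length, 0L) == 0)) stop("every group must be non-empty")
  ref <- groups[[reference]]
  mref <- mean(ref)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    pc <- 100 * (mean(x) - mref) / mref
    if (g == reference || length(x) < 2 || length(ref) < 2) {
      tt <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      # degenerate zero-variance input leaves the test undefined (NA)
      tt <- tryCatch(compare_groups(x, ref, welch = welch),
                     error = function(e) list(t = NA_real_, df = NA_real_,
                                              p = NA_real_))
    }
    data.frame(group = g, mean_nm = mean(x),
               sd_nm = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x), percent_change = pc,
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), reference = reference),
            class = "spacing_summary")
}

#' @export
print.spacing_summary <- function(x, ...) {
  cat(sprintf("inter-layer spacing summary (reference: %s)\n", x$reference))
  print(x$table, row.names = FALSE)
  invisible(x)
}
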
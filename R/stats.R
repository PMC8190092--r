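#' Patchiness of a periphery profile
#'
#' Summary statistic for how unevenly a fluorescence signal is distributed
#' along the cell periphery: the population standard deviation of the
#' profile values normalised by their total. Evenly distributed fluorescence
#' gives a low value, patchy fluorescence a high one. Because the total
#' grows with the number of samples, the statistic is only comparable across
#' cells profiled at the same `n` (the package default is 360); an
#' alternative normaliser divides by the mean instead (a plain coefficient
#' of variation, independent of `n`).
#'
#' @param profile a `periphery_profile`.
#' @param normalizer `"total"` (SD / sum, default) or `"mean"` (SD / mean).
#' @return list of class `patchiness_value`: `value`, `n`, `channel`,
#'   `normalizer`.
#' @export
patchiness <- function(profile, normalizer = c("total", "mean")) {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(profile, "periphery_profile"))
  v <- profile$value
  if (sum(v) <= 0) stop("patchiness undefined for a profile with zero total")
  s <- sd_pop(v)
  value <- if (normalizer == "total") s / sum(v) else s / mean(v)
  structure(list(value = value, n = profile$n, channel = profile$channel,
                 normalizer = normalizer),
            class = "patchiness_value")
}

#' Longitudinal-side asymmetry of a periphery profile
#'
#' Ratio of the maximum fluorescence on the two longitudinal sides,
#' reported as brighter over dimmer (so always >= 1) together with which
#' side was brighter. Order-free by construction: swapping the L1/L2
#' anchoring cannot change the value.
#'
#' @param profile a `periphery_profile` with regions assigned
#'   ([partition_regions()]).
#' @return list of class `asymmetry_value`: `value` (>= 1),
#'   `brighter_side` (`"L1"` or `"L2"`), per-side maxima `max_L1`, `max_L2`.
#' @export
side_asymmetry <- function(profile) {
  stopifnot(inherits(profile, "periphery_profile"))
  if (anyNA(profile$region)) stop("profile has no region labels; run partition_regions()")
  m1 <- suppressWarnings(max(profile$value[profile$region == "L1"]))
  m2 <- suppressWarnings(max(profile$value[profile$region == "L2"]))
  if (!is.finite(m1) || !is.finite(m2))
    stop("both longitudinal sides must be non-empty")
  if (m1 <= 0 || m2 <= 0) stop("side maxima must be positive")
  structure(list(value = max(m1, m2) / min(m1, m2),
                 brighter_side = if (m1 >= m2) "L1" else "L2",
                 max_L1 = m1, max_L2 = m2),
            class = "asymmetry_value")
}

#' Pearson colocalization of two channels within a cell mask
#'
#' Pearson correlation coefficient of the two intensities over in-mask
#' pixels (no Costes thresholding).
#'
#' @param ch1,ch2 numeric matrices of identical dimension.
#' @param mask a `cell_mask` or logical matrix.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(identical(dim(ch1), dim(ch2)), identical(dim(ch1), dim(m)))
  x <- ch1[m]; y <- ch2[m]
  if (length(x) == 0) stop("empty mask")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance within mask; correlation undefined")
  stats::cor(x, y)
}

#' Manders overlap coefficients (zero thresholds)
#'
#' Optional companions to [pearson_colocalization()]: `M1` is the fraction
#' of channel-1 intensity in pixels where channel 2 exceeds its threshold,
#' and vice versa for `M2`.
#'
#' @inheritParams pearson_colocalization
#' @param thr1,thr2 channel thresholds (default 0).
#' @return named numeric vector `c(M1, M2)`.
#' @export
manders_coefficients <- function(ch1, ch2, mask, thr1 = 0, thr2 = 0) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  x <- ch1[m]; y <- ch2[m]
  if (sum(x) <= 0 || sum(y) <= 0) stop("channels must have positive in-mask totals")
  c(M1 = sum(x[y > thr2]) / sum(x), M2 = sum(y[x > thr1]) / sum(y))
}

#' Two-sided two-sample t test
#'
#' Pooled-variance Student t by default (`welch = TRUE` switches to the
#' Welch unequal-variance form). Degenerate zero-variance input with equal
#' means returns `t = 0, p = 1`; with unequal means it is an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch logical; use the Welch correction.
#' @return list of class `group_test`: `t`, `df`, `p` (two-sided),
#'   `mean_x`, `mean_y`.
#' @export
compare_groups <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            mean_x = mean(x), mean_y = mean(y)),
                       class = "group_test"))
    stop("zero variance with unequal means: t statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_x = mean(x), mean_y = mean(y)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("two-sided two-sample t test: t = %.4f, df = %.2f, p = %.3g\n",
              x$t, x$df, x$p))
  invisible(x)
}
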
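#' Chlorophyll a from a methanol extract
#'
#' Chlorophyll concentration of a 90% methanol extract from its optical
#' density at 665 nm, `12.7 * OD665` (extract units per OD unit).
#'
#' @param od665 absorbance at 665 nm (>= 0).
#' @return chlorophyll concentration, `12.7 * od665`.
#' @export
chl_methanol <- function(od665) {
  stopifnot(is.numeric(od665))
  if (any(od665 < 0)) stop("OD665 must be non-negative")
  12.7 * od665
}

#' Whole-cell chlorophyll from absorbance readings
#'
#' Corrects the 678 nm chlorophyll peak for phycobilin overlap,
#' `A_Chl678 = 1.0162 * A_678 - 0.0630 * A_625`, and converts to a molar
#' concentration with the absorption coefficient 68 mM^-1 cm^-1:
#' `c = A_Chl678 / (68 * pathlength)`. A negative corrected absorbance is
#' inconsistent with the calibration and is flagged rather than silently
#' returned.
#'
#' @param a678 absorbance at 678 nm.
#' @param a625 absorbance at 625 nm.
#' @param pathlength_cm cuvette path length in cm (> 0).
#' @param a750 optional turbidity reading at 750 nm; when
#'   `turbidity_correct = TRUE` it is subtracted from both absorbances
#'   before the formula (off by default; the calibration formula expects
#'   raw readings).
#' @param turbidity_correct logical, see `a750`.
#' @return list of class `chl_wholecell`: `a_chl678` (corrected
#'   absorbance), `chl_mM` (concentration), `flagged` (TRUE when
#'   `a_chl678 < 0`, concentration then `NA`).
#' @export
chl_whole_cell <- function(a678, a625, pathlength_cm = 1, a750 = 0,
                           turbidity_correct = FALSE) {
  stopifnot(pathlength_cm > 0, a678 >= 0, a625 >= 0)
  if (turbidity_correct) { a678 <- a678 - a750; a625 <- a625 - a750 }
  a_chl <- 1.0162 * a678 - 0.0630 * a625
  flagged <- a_chl < 0
  if (flagged)
    warning("corrected A_Chl678 is negative; inputs inconsistent with the calibration")
  structure(list(a_chl678 = a_chl,
                 chl_mM = if (flagged) NA_real_ else a_chl / (68 * pathlength_cm),
                 flagged = flagged),
            class = "chl_wholecell")
}

#' 77 K fluorescence emission spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths (nm), nominally
#'   620-750.
#' @param intensity emission intensities.
#' @param excitation_nm 435 (chlorophyll a excitation) or 600 (phycocyanin
#'   excitation); determines the normalisation anchor.
#' @return list of class `spectrum_77k`.
#' @export
spectrum_77k <- function(wavelength_nm, intensity, excitation_nm = 435) {
  stopifnot(length(wavelength_nm) == length(intensity),
            all(diff(wavelength_nm) > 0),
            excitation_nm %in% c(435, 600))
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity),
                 excitation_nm = excitation_nm,
                 background = 0, normalized = FALSE),
            class = "spectrum_77k")
}

#' Normalise a 77 K emission spectrum
#'
#' Subtracts a background (a configured constant, or the spectrum minimum
#' within its range when `background = "min"`), then divides by the maximum
#' within the excitation-specific anchor window: the PSI emission peak
#' (710-730 nm) for 435 nm excitation, the phycocyanin peak (645-665 nm)
#' for 600 nm excitation. The anchor peak value is exactly 1 afterwards.
#' With zero background the operation is idempotent.
#'
#' @param spectrum a [spectrum_77k()].
#' @param background numeric constant to subtract, or `"min"`.
#' @return normalised `spectrum_77k` (fields `background` and `normalized`
#'   updated; `anchor_nm` records the peak position used).
#' @export
normalize_77k <- function(spectrum, background = 0) {
  stopifnot(inherits(spectrum, "spectrum_77k"))
  bg <- if (identical(background, "min")) min(spectrum$intensity)
        else as.numeric(background)
  y <- spectrum$intensity - bg
  win <- if (spectrum$excitation_nm == 435) c(710, 730) else c(645, 665)
  i <- spectrum$wavelength_nm >= win[1] & spectrum$wavelength_nm <= win[2]
  if (!any(i)) stop("anchor window ", win[1], "-", win[2],
                    " nm not covered by the spectrum")
  peak <- max(y[i])
  if (peak <= 0) stop("non-positive anchor peak after background subtraction")
  spectrum$intensity <- y / peak
  spectrum$background <- bg
  spectrum$normalized <- TRUE
  spectrum$anchor_nm <- spectrum$wavelength_nm[i][which.max(y[i])]
  spectrum
}
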
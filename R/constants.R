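# Pinned numerical constants used across the pipeline.

#' Pipeline constants
#'
#' Versioned numerical constants: Daubechies-5 analysis filters for the
#' motion-correction wavelet transform, hemoglobin extinction coefficients
#' (Gratzer/Cope tabulation) at the two acquisition wavelengths, default
#' differential path-length factors, the Morlet mother-wavelet parameter and
#' the hemodynamic analysis band.
#'
#' @format A named list:
#' \describe{
#'   \item{db5_dec_lo, db5_dec_hi}{Daubechies-5 decomposition filters
#'     (scaling / wavelet), 10 taps each, orthonormal.}
#'   \item{extinction}{2 x 2 matrix of extinction coefficients in
#'     1/(mM*cm); rows = wavelengths (760, 850 nm), columns = chromophores
#'     (HbO, HbR).}
#'   \item{dpf_default}{Differential path-length factor per wavelength
#'     (dimensionless), default 6.0 at both wavelengths.}
#'   \item{wavelengths_nm}{Acquisition wavelengths (nm).}
#'   \item{omega0}{Morlet mother-wavelet nondimensional frequency (6).}
#'   \item{band_hz}{Hemodynamic coherence band, Hz (0.015-0.15).}
#'   \item{roi_levels}{The region-of-interest vocabulary.}
#' }
#' @export
hypersync_constants <- list(
  # Daubechies 5 (10-tap) orthonormal decomposition filters.
  db5_dec_lo = c(
    0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
    0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
    0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
    0.16010239797419293),
  db5_dec_hi = c(
    -0.16010239797419293, 0.60382926979718965, -0.72430852843777294,
    0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
    -0.077571493840045719, -0.0062414902127982744, 0.012580751999081999,
    0.0033357252854737712),
  # Extinction coefficients, 1/(mM*cm): rows 760/850 nm, cols HbO/HbR.
  extinction = matrix(
    c(0.58600, 1.54852,
      1.05800, 0.69132),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("760", "850"), c("HbO", "HbR"))),
  dpf_default = c("760" = 6.0, "850" = 6.0),
  wavelengths_nm = c(760, 850),
  omega0 = 6,
  band_hz = c(0.015, 0.15),
  roi_levels = c("L.IFG", "R.IFG", "dmPFC")
)

# Conditions of the dyadic movement task: back-to-back rest, free movement,
# intentional synchrony.
CONDITION_LEVELS <- c("BB", "FM", "IS")

`%||%` <- function(a, b) if (is.null(a)) b else a
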
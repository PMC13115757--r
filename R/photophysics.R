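#' Steady-state anisotropy from polarized intensities (L-format)
#'
#' \deqn{r = \frac{I_{VV} - G I_{VH}}{I_{VV} + 2 G I_{VH}}}
#' where \eqn{G} is the instrumental correction factor of the L-format
#' (single emission channel) geometry. Note the plus sign in the
#' denominator: the total intensity of an ideal dipole emitter is
#' \eqn{I_{VV} + 2 I_{VH}}; formulations that print a minus sign there are
#' typographical errors against the standard L-format expression.
#'
#' @param I_VV Intensity with both polarizers vertical (counts, >= 0).
#' @param I_VH Vertical excitation, horizontal emission (counts, >= 0).
#' @param G Instrumental G factor, > 0.
#' @return Anisotropy in (-0.5, 1]. Vectorised over intensities.
#' @export
#' @examples
#' anisotropy_from_intensities(2, 1, 1)  # 0.25
anisotropy_from_intensities <- function(I_VV, I_VH, G = 1) {
  .check_numeric_vec(I_VV, "I_VV")
  .check_numeric_vec(I_VH, "I_VH")
  .check_positive(G, "G")
  if (any(I_VV < 0) || any(I_VH < 0))
    .stop_domain("intensities must be non-negative")
  den <- I_VV + 2 * G * I_VH
  if (any(den == 0))
    .stop_domain("zero total intensity: both polarized intensities are zero")
  (I_VV - G * I_VH) / den
}

#' Polarized intensities consistent with a given anisotropy
#'
#' Inverse of [anisotropy_from_intensities()], used by the synthetic
#' generators: splits a total intensity \eqn{I_T = I_{VV} + 2 G I_{VH}}
#' into the polarized components that reproduce anisotropy `r`.
#'
#' @param r Anisotropy in (-0.5, 1].
#' @param total Total intensity \eqn{I_{VV} + 2 G I_{VH}}.
#' @param G Instrumental G factor.
#' @return List with `I_VV` and `I_VH`.
#' @export
polarized_intensities <- function(r, total, G = 1) {
  if (any(r <= -0.5) || any(r > 1)) .stop_domain("`r` outside (-0.5, 1]")
  if (any(total <= 0)) .stop_domain("`total` must be positive")
  I_VV <- total * (1 + 2 * r) / 3
  I_VH <- total * (1 - r) / (3 * G)
  list(I_VV = I_VV, I_VH = I_VH)
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' For a multi-exponential decay \eqn{I(t) = \sum_i A_i e^{-t/\tau_i}} the
#' weighted average lifetime is
#' \deqn{\langle\tau\rangle = \frac{\sum_i A_i \tau_i^2}
#'                                 {\sum_i A_i \tau_i}.}
#' Homogeneous of degree zero in the amplitudes, and always bounded by the
#' smallest and largest component lifetimes.
#'
#' @param amplitudes Pre-exponential factors, >= 0, not all zero.
#' @param lifetimes Component lifetimes, ns, > 0.
#' @return Mean lifetime, ns.
#' @export
#' @examples
#' weighted_mean_lifetime(c(0.5, 0.5), c(2, 4))  # 10/3 ns
weighted_mean_lifetime <- function(amplitudes, lifetimes) {
  .check_numeric_vec(amplitudes, "amplitudes")
  .check_numeric_vec(lifetimes, "lifetimes")
  if (length(amplitudes) != length(lifetimes))
    .stop_domain("`amplitudes` and `lifetimes` must have equal length")
  if (any(amplitudes < 0)) .stop_domain("`amplitudes` must be non-negative")
  if (all(amplitudes == 0)) .stop_domain("`amplitudes` must not all be zero")
  if (any(lifetimes <= 0)) .stop_domain("`lifetimes` must be positive")
  sum(amplitudes * lifetimes^2) / sum(amplitudes * lifetimes)
}

#' Emission peak position and band shift
#'
#' `peak_wavelength()` locates the emission maximum of a spectrum by a
#' parabolic (three-point) interpolation around the highest sample, which
#' resolves the peak to better than the wavelength step.
#' `emission_shift()` is the difference in peak position between two
#' spectra (positive = red shift of `b` relative to `a`), e.g. the
#' lactone-to-carboxylate shift of camptothecin on deprotonation.
#'
#' @param wavelength Wavelengths, nm, strictly increasing.
#' @param intensity Spectrum intensities, same length.
#' @return Peak wavelength in nm.
#' @export
peak_wavelength <- function(wavelength, intensity) {
  .check_numeric_vec(wavelength, "wavelength", 3L)
  .check_numeric_vec(intensity, "intensity", 3L)
  if (length(wavelength) != length(intensity))
    .stop_domain("`wavelength` and `intensity` must have equal length")
  i <- which.max(intensity)
  if (i == 1L || i == length(intensity)) return(wavelength[i])
  y <- intensity[(i - 1):(i + 1)]
  x <- wavelength[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom == 0) return(x[2])
  x[2] + 0.5 * (x[2] - x[1]) * (y[1] - y[3]) / denom
}

#' @param a,b Spectra as data frames / lists with `wavelength` and
#'   `intensity` elements.
#' @rdname peak_wavelength
#' @export
emission_shift <- function(a, b) {
  peak_wavelength(b$wavelength, b$intensity) -
    peak_wavelength(a$wavelength, a$intensity)
}
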
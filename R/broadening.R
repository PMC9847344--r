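## Gas constant in kcal mol^-1 K^-1 (CODATA).
R_KCAL <- 1.98720425864083e-3

#' Band-shape parameters
#'
#' Both the Lorentzian and the Gaussian are height-parameterized with a common
#' full width at half maximum, so the pair (I, w) has identical meaning across
#' shapes and mixing values: the band value at `x0` is `I` and the value at
#' `x0 +- w/2` is `I/2` for every `eta`.
#'
#' @param shape `"lorentzian"`, `"gaussian"`, or `"pseudo_voigt"`.
#' @param fwhm Full width at half maximum in cm^-1; the default 12 cm^-1 is
#'   the customary broadening for harmonic line spectra in the fingerprint
#'   region.
#' @param eta Lorentzian fraction in \[0, 1\]; used when `shape` is
#'   `"pseudo_voigt"`.
#' @return An object of class `band_shape`.
#' @export
band_shape <- function(shape = c("lorentzian", "gaussian", "pseudo_voigt"),
                       fwhm = 12, eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  eta <- switch(shape, lorentzian = 1, gaussian = 0, pseudo_voigt = eta)
  structure(list(shape = shape, fwhm = fwhm, eta = eta), class = "band_shape")
}

#' Boltzmann weights from relative free energies
#'
#' Computes `w_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` with the usual
#' max-shift for numerical safety. Weights are invariant under adding any
#' constant to all energies and sum to one.
#'
#' @param dG Numeric vector of relative (free) energies in kcal/mol.
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Numeric vector of weights summing to 1.
#' @export
boltzmann_weights <- function(dG, temperature = 298.15) {
  if (length(dG) == 0L) stop("empty energy list", call. = FALSE)
  if (!all(is.finite(dG))) stop("energies must be finite", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  z <- -(dG - min(dG)) / (R_KCAL * temperature)
  e <- exp(z)
  e / sum(e)
}

## Height-parameterized Lorentzian / Gaussian with common FWHM w.
lorentz_profile <- function(x, x0, I, w) {
  I / (1 + (2 * (x - x0) / w)^2)
}

gauss_profile <- function(x, x0, I, w) {
  I * exp(-4 * log(2) * ((x - x0) / w)^2)
}

#' Evaluate one pseudo-Voigt band
#'
#' `V(x) = eta * L(x) + (1 - eta) * G(x)` with both components sharing the
#' height `I` and FWHM `w`, so `V(x0) = I` for any mixing `eta`.
#'
#' @param x Wavenumber(s) at which to evaluate, cm^-1.
#' @param x0 Band position, cm^-1.
#' @param I Band height.
#' @param w FWHM in cm^-1, > 0.
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return Band value(s) at `x`.
#' @export
band_value <- function(x, x0, I, w, eta = 1) {
  if (any(w <= 0)) stop("bandwidth w must be > 0", call. = FALSE)
  eta * lorentz_profile(x, x0, I, w) + (1 - eta) * gauss_profile(x, x0, I, w)
}

#' Default evaluation grid for broadened theoretical spectra
#'
#' The analysis window padded by three FWHM on each side (so bands near the
#' window edge are not truncated), at 1 cm^-1 steps by default.
#'
#' @param lo,hi Analysis window bounds in cm^-1.
#' @param fwhm Broadening FWHM used for the padding.
#' @param step Grid step in cm^-1.
#' @return Numeric wavenumber grid.
#' @export
default_grid <- function(lo, hi, fwhm = 12, step = 1) {
  seq(lo - 3 * fwhm, hi + 3 * fwhm, by = step)
}

#' Broaden a line spectrum onto a grid
#'
#' Each stick becomes one band of the requested shape; the continuous value is
#' the pointwise sum over all bands. Broadening is linear in the line list and
#' homogeneous in intensity. An empty line spectrum yields an all-zero
#' spectrum.
#'
#' @param line A [line_spectrum()].
#' @param shape A [band_shape()].
#' @param grid Ascending wavenumber grid.
#' @return A [continuous_spectrum()] on `grid`.
#' @export
broaden <- function(line, shape = band_shape(), grid) {
  vals <- numeric(length(grid))
  for (i in seq_along(line$wavenumber)) {
    vals <- vals + band_value(grid, line$wavenumber[i], line$intensity[i],
                              shape$fwhm, shape$eta)
  }
  continuous_spectrum(grid, vals, line$modality)
}

#' Boltzmann-weighted ensemble spectrum
#'
#' Broadened per-conformer spectra are combined with Boltzmann weights from
#' the conformers' relative free energies at the ensemble temperature.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param modality Which modality to broaden.
#' @param shape A [band_shape()].
#' @param grid Wavenumber grid.
#' @return A [continuous_spectrum()].
#' @export
ensemble_spectrum <- function(ensemble, modality, shape = band_shape(), grid) {
  modality <- as_modality(modality)
  if (!modality %in% ensemble$modalities) {
    stop("ensemble '", ensemble$isomer_id, "' has no ", modality, " spectra",
         call. = FALSE)
  }
  wts <- boltzmann_weights(
    vapply(ensemble$conformers, `[[`, numeric(1), "dG"),
    ensemble$temperature)
  vals <- numeric(length(grid))
  for (i in seq_along(ensemble$conformers)) {
    s <- broaden(ensemble$conformers[[i]]$spectra[[modality]], shape, grid)
    vals <- vals + wts[i] * s$intensity
  }
  continuous_spectrum(grid, vals, modality)
}
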
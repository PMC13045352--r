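FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # FWHM = 2*sqrt(2 ln 2) * sigma

#' Anisotropic Gaussian point-spread-function model
#'
#' Confocal/Airyscan-style PSF approximated by an anisotropic 3D Gaussian with
#' a lateral sigma (x and y) and an axial sigma (z). With `normalize = TRUE`
#' a rendered point source integrates to its source intensity; otherwise the
#' peak voxel carries the source intensity.
#'
#' @param sigma_lateral Lateral standard deviation in nm (> 0).
#' @param sigma_axial Axial standard deviation in nm (> 0).
#' @param normalize Logical; conserve integrated intensity (default) or peak.
#' @return Object of class `psf_model`.
#' @examples
#' p <- psf_model(75, 250)
#' psf_fwhm(p)  # c(lateral = 176.6, axial = 588.7) approximately
#' @export
psf_model <- function(sigma_lateral, sigma_axial, normalize = TRUE) {
  structure(list(
    sigma_lateral = check_scalar(sigma_lateral, "sigma_lateral", positive = TRUE),
    sigma_axial = check_scalar(sigma_axial, "sigma_axial", positive = TRUE),
    normalize = isTRUE(normalize)), class = "psf_model")
}

#' Full width at half maximum of a PSF model
#'
#' @param psf A [psf_model].
#' @return Named vector `c(lateral, axial)` in nm, using
#'   `FWHM = 2*sqrt(2*ln 2)*sigma`.
#' @export
psf_fwhm <- function(psf) {
  stopifnot(inherits(psf, "psf_model"))
  c(lateral = FWHM_FACTOR * psf$sigma_lateral,
    axial = FWHM_FACTOR * psf$sigma_axial)
}

#' Convert a FWHM to the Gaussian sigma
#' @param fwhm Full width at half maximum (nm).
#' @return Sigma in nm.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

#' Effective PSF width after expansion
#'
#' Expansion microscopy divides the effective PSF by the expansion factor:
#' a 170 nm lateral FWHM imaged through a 10x gel behaves like a 17 nm probe
#' on the biological (pre-expansion) scale.
#'
#' @param fwhm Measured FWHM in nm (> 0).
#' @param ef Expansion factor (> 0).
#' @return Effective FWHM in nm on the biological scale.
#' @examples
#' effective_psf(170, 10)  # 17
#' @export
effective_psf <- function(fwhm, ef) {
  check_scalar(fwhm, "fwhm", positive = TRUE)
  check_scalar(ef, "ef", positive = TRUE)
  fwhm / ef
}
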
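#' Camera and optics model for synthetic scene rendering
#'
#' Bundles the acquisition parameters used by all synthetic generators: pixel
#' size, an isotropic Gaussian approximation of the point-spread function,
#' the expected photon yield per fluorophore, background (flat level plus an
#' optional linear ramp), and a minimal camera model (constant offset plus
#' Gaussian read noise, one count per detected photon).
#'
#' @param pixel_size Pixel size in micrometres per pixel. Must be positive.
#' @param psf_sigma Standard deviation of the Gaussian PSF, in pixels.
#' @param photons_per_fluorophore Expected integrated photon flux contributed
#'   by one fluorophore over the exposure.
#' @param background_level Mean background, photons per pixel.
#' @param background_gradient Linear background ramp along x, photons per
#'   pixel per pixel of distance from the left image edge. Use 0 for a flat
#'   background.
#' @param camera_offset Constant camera offset added to every pixel, counts.
#' @param read_noise_sd Standard deviation of Gaussian read noise, counts.
#' @param shot_noise Logical; apply Poisson shot noise to the expected photon
#'   image. Disable to render noise-free scenes for exact flux checks.
#'
#' @return An object of class `optics_model` (a validated list).
#' @examples
#' op <- optics_model(pixel_size = 0.1, psf_sigma = 1)
#' op
#' @export
optics_model <- function(pixel_size = 0.1,
                         psf_sigma = 1.0,
                         photons_per_fluorophore = 100,
                         background_level = 50,
                         background_gradient = 0,
                         camera_offset = 100,
                         read_noise_sd = 2,
                         shot_noise = TRUE) {
  stopifnot(
    "pixel_size must be > 0" = is.numeric(pixel_size) && pixel_size > 0,
    "psf_sigma must be > 0" = is.numeric(psf_sigma) && psf_sigma > 0,
    "photons_per_fluorophore must be >= 0" = photons_per_fluorophore >= 0,
    "background_level must be >= 0" = background_level >= 0,
    "read_noise_sd must be >= 0" = read_noise_sd >= 0,
    "shot_noise must be TRUE or FALSE" = isTRUE(shot_noise) || isFALSE(shot_noise)
  )
  structure(
    list(
      pixel_size = pixel_size,
      psf_sigma = psf_sigma,
      photons_per_fluorophore = photons_per_fluorophore,
      background_level = background_level,
      background_gradient = background_gradient,
      camera_offset = camera_offset,
      read_noise_sd = read_noise_sd,
      shot_noise = shot_noise
    ),
    class = "optics_model"
  )
}

#' @export
print.optics_model <- function(x, ...) {
  cat("Optics model\n")
  cat(sprintf("  pixel size       : %g um/px\n", x$pixel_size))
  cat(sprintf("  PSF sigma        : %g px\n", x$psf_sigma))
  cat(sprintf("  photons/fluor.   : %g\n", x$photons_per_fluorophore))
  cat(sprintf("  background       : %g + %g*x photons/px\n",
              x$background_level, x$background_gradient))
  cat(sprintf("  camera offset    : %g counts, read noise sd %g\n",
              x$camera_offset, x$read_noise_sd))
  cat(sprintf("  shot noise       : %s\n", if (x$shot_noise) "on" else "off"))
  invisible(x)
}
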
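# Rendering internals shared by the synthetic-scene generators.
#
# Image convention: a numeric matrix with nrow = ny and ncol = nx; pixel
# centres sit at integer coordinates, 0-based, origin at the centre of the
# top-left pixel.  Pixel (x, y) is image[y + 1, x + 1].  Physical positions
# are x_um = x_px * pixel_size.

# Integrated 2-D Gaussian PSF: each pixel receives the flux integrated over
# its unit square (difference of normal CDFs at the pixel edges), so total
# flux is conserved on the grid regardless of sub-pixel position.
add_gaussian_spot <- function(img, x_px, y_px, flux, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(6 * sigma)
  xs <- max(0, floor(x_px) - r):min(nx - 1, ceiling(x_px) + r)
  ys <- max(0, floor(y_px) - r):min(ny - 1, ceiling(y_px) + r)
  if (!length(xs) || !length(ys)) return(img)
  fx <- stats::pnorm(xs + 0.5, x_px, sigma) - stats::pnorm(xs - 0.5, x_px, sigma)
  fy <- stats::pnorm(ys + 0.5, y_px, sigma) - stats::pnorm(ys - 0.5, y_px, sigma)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + flux * outer(fy, fx)
  img
}

# Expected photon image: flat background + linear ramp along x + spots.
expected_photon_image <- function(field_size, optics, spots) {
  ny <- field_size[1]; nx <- field_size[2]
  ramp <- optics$background_level + optics$background_gradient * (seq_len(nx) - 1)
  img <- matrix(ramp, nrow = ny, ncol = nx, byrow = TRUE)
  if (!is.null(spots) && nrow(spots)) {
    for (k in seq_len(nrow(spots))) {
      img <- add_gaussian_spot(img, spots$x_px[k], spots$y_px[k],
                               spots$flux[k], optics$psf_sigma)
    }
  }
  img
}

# Camera model: Poisson shot noise on expected photons (optional), then
# Gaussian read noise and a constant offset, in counts (unit gain).
apply_camera <- function(expected, optics) {
  counts <- if (optics$shot_noise) {
    matrix(stats::rpois(length(expected), lambda = as.vector(expected)),
           nrow = nrow(expected))
  } else {
    expected
  }
  if (optics$read_noise_sd > 0) {
    counts <- counts + matrix(
      stats::rnorm(length(counts), 0, optics$read_noise_sd),
      nrow = nrow(counts))
  }
  counts + optics$camera_offset
}

# Rejection-sample n points with pairwise separation >= min_sep inside
# [margin, nx-1-margin] x [margin, ny-1-margin] (pixel units).
place_points <- function(n, field_size, min_sep, margin = 0,
                         max_tries = 5000L) {
  ny <- field_size[1]; nx <- field_size[2]
  lo_x <- margin; hi_x <- nx - 1 - margin
  lo_y <- margin; hi_y <- ny - 1 - margin
  if (hi_x <= lo_x || hi_y <= lo_y) {
    stop("field of ", nx, "x", ny,
         " px is too small for the requested margin of ", margin, " px")
  }
  xs <- numeric(n); ys <- numeric(n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, lo_x, hi_x)
      y <- stats::runif(1, lo_y, hi_y)
      if (k == 1L ||
          all((xs[seq_len(k - 1)] - x)^2 + (ys[seq_len(k - 1)] - y)^2 >=
              min_sep^2)) {
        xs[k] <- x; ys[k] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place ", n, " spots with min_separation = ", min_sep,
           " px in a ", nx, "x", ny, " px field (placed ", k - 1, ")")
    }
  }
  cbind(x = xs, y = ys)
}
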
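#' Ellipsoid surface area from tri-axial virion dimensions
#'
#' Computes the surface area of a tri-axial ellipsoid from its full axis
#' lengths (e.g. virion dimensions measured by cryo-electron tomography)
#' using the Thomsen approximation
#' `S = 4*pi*((a^p*b^p + a^p*c^p + b^p*c^p)/3)^(1/p)` with `p = 1.6075` and
#' `a, b, c` the semi-axes. The approximation is exact for a sphere and
#' accurate to well under 2% for moderate axis ratios; a numerical
#' quadrature of the parametrised surface is available for verification.
#'
#' @param dims Numeric length-3 vector of full axis lengths in nanometres
#'   (order irrelevant), e.g. `c(350, 280, 200)`.
#' @param method `"thomsen"` (default) or `"quadrature"` (dense trapezoid
#'   integration of the surface element).
#' @return Surface area in nm^2.
#' @examples
#' ellipsoid_surface_area(c(350, 280, 200))  # IMV: ~238446 nm^2
#' ellipsoid_surface_area(c(440, 380, 260))  # IEV: ~405037 nm^2
#' @export
ellipsoid_surface_area <- function(dims, method = c("thomsen", "quadrature")) {
  method <- match.arg(method)
  stopifnot(length(dims) == 3)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all ellipsoid axes must be positive")
  }
  semi <- dims / 2
  a <- semi[1]; b <- semi[2]; c_ <- semi[3]
  if (method == "thomsen") {
    p <- 1.6075
    4 * pi * (((a * b)^p + (a * c_)^p + (b * c_)^p) / 3)^(1 / p)
  } else {
    # S = int_0^pi int_0^2pi |r_theta x r_phi| dphi dtheta, trapezoid grid
    n_th <- 2000L; n_ph <- 2000L
    th <- seq(0, pi, length.out = n_th)
    ph <- seq(0, 2 * pi, length.out = n_ph)
    st <- sin(th); ct <- cos(th)
    sp <- sin(ph); cp <- cos(ph)
    # |r_theta x r_phi| for r = (a st cp, b st sp, c ct)
    el <- outer(st, rep(1, n_ph)) * sqrt(
      (b * c_)^2 * outer(st^2, cp^2) +
      (a * c_)^2 * outer(st^2, sp^2) +
      (a * b)^2 * outer(ct^2, rep(1, n_ph)))
    wth <- rep(pi / (n_th - 1), n_th); wth[c(1, n_th)] <- wth[1] / 2
    wph <- rep(2 * pi / (n_ph - 1), n_ph); wph[c(1, n_ph)] <- wph[1] / 2
    as.numeric(t(wth) %*% el %*% wph)
  }
}

#' Membrane surface area available per motor complex
#'
#' Integer part (floor) of `surface_area / n_complexes`: the average patch of
#' virion surface per recruited motor complex. Floor rather than round is
#' used so the reported density is a whole number of nm^2 that the virion
#' surface can actually provide per complex.
#'
#' @param surface_area Surface area in nm^2.
#' @param n_complexes Number of motor complexes (>= 1).
#' @return Integer nm^2 per complex.
#' @examples
#' area_per_motor(238446, 139)  # 1715
#' area_per_motor(405037, 320)  # 1265
#' @export
area_per_motor <- function(surface_area, n_complexes) {
  stopifnot(surface_area > 0)
  if (any(n_complexes < 1)) stop("n_complexes must be >= 1")
  floor(surface_area / n_complexes)
}
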
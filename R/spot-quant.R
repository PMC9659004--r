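#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Computes a scale-normalised Laplacian-of-Gaussian response at the scale
#' matched to `estimated_diameter` (sigma = d / (2*sqrt(2)), the scale at
#' which a blob of that diameter maximises the response), finds local maxima
#' of the (sign-flipped, so bright blobs score positive) response, and keeps
#' those at or above `quality_threshold`. Sub-pixel refinement fits a 1-D
#' quadratic through the response of each maximum and its neighbours.
#'
#' @param image Numeric matrix.
#' @param estimated_diameter Expected spot diameter in pixels (>= 3).
#' @param quality_threshold Minimum LoG response magnitude to keep a maximum.
#' @param use_median_filter Apply a 3x3 median filter before detection.
#' @param subpixel Refine centroids by quadratic interpolation.
#' @return Data frame with `x_px`, `y_px` (0-based centroids) and `quality`.
#' @export
detect_spots <- function(image, estimated_diameter, quality_threshold = 0,
                         use_median_filter = FALSE, subpixel = TRUE) {
  stopifnot(is.matrix(image), estimated_diameter >= 3)
  if (estimated_diameter > min(dim(image))) {
    stop("estimated_diameter (", estimated_diameter,
         " px) exceeds the image size")
  }
  if (use_median_filter) image <- median3x3(image)
  sigma <- estimated_diameter / (2 * sqrt(2))
  resp <- log_response(image, sigma)
  ny <- nrow(resp); nx <- ncol(resp)

  # strict local maxima over the 8-neighbourhood (ties broken to the
  # earlier pixel by using >= against later neighbours)
  is_max <- matrix(TRUE, ny, nx)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- resp
  for (k in seq_len(nrow(shifts))) {
    nb <- pad[2:(ny + 1) + shifts$dy[k], 2:(nx + 1) + shifts$dx[k]]
    is_max <- is_max & (resp > nb | (resp == nb &
      (shifts$dy[k] > 0 | (shifts$dy[k] == 0 & shifts$dx[k] > 0))))
  }
  is_max <- is_max & resp >= quality_threshold
  # exclude the 1-px border (no full neighbourhood)
  is_max[c(1, ny), ] <- FALSE
  is_max[, c(1, nx)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      quality = numeric(0)))
  }
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  qual <- resp[idx]
  if (subpixel) {
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      cx <- resp[r, c]
      den_x <- resp[r, c - 1] + resp[r, c + 1] - 2 * cx
      den_y <- resp[r - 1, c] + resp[r + 1, c] - 2 * cx
      if (den_x < 0) xs[k] <- xs[k] + 0.5 * (resp[r, c - 1] - resp[r, c + 1]) / den_x
      if (den_y < 0) ys[k] <- ys[k] + 0.5 * (resp[r - 1, c] - resp[r + 1, c]) / den_y
    }
  }
  out <- data.frame(x_px = xs, y_px = ys, quality = qual)
  out[order(-out$quality), , drop = FALSE]
}

# separable Gaussian smoothing via banded row/column operators
gaussian_smooth <- function(image, sigma) {
  ny <- nrow(image); nx <- ncol(image)
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-half:half, 0, sigma)
  smooth_dim <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- max(1, i - half):min(n, i + half)
      w <- kern[js - i + half + 1]
      M[i, js] <- w / sum(w) # renormalised at borders (replicate-like)
    }
    M
  }
  smooth_dim(ny) %*% image %*% t(smooth_dim(nx))
}

# scale-normalised LoG response, sign-flipped so bright blobs are positive
log_response <- function(image, sigma) {
  g <- gaussian_smooth(image, sigma)
  ny <- nrow(g); nx <- ncol(g)
  pad <- matrix(0, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- g
  pad[1, ] <- pad[2, ]; pad[ny + 2, ] <- pad[ny + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nx + 2] <- pad[, nx + 1]
  lap <- pad[1:ny, 2:(nx + 1)] + pad[3:(ny + 2), 2:(nx + 1)] +
    pad[2:(ny + 1), 1:nx] + pad[2:(ny + 1), 3:(nx + 2)] - 4 * g
  -sigma^2 * lap
}

median3x3 <- function(image) {
  ny <- nrow(image); nx <- ncol(image)
  pad <- matrix(NA_real_, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- image
  pad[1, ] <- pad[2, ]; pad[ny + 2, ] <- pad[ny + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nx + 2] <- pad[, nx + 1]
  stack <- sapply(seq_len(9), function(k) {
    dy <- (k - 1) %% 3; dx <- (k - 1) %/% 3
    as.vector(pad[(1:ny) + dy, (1:nx) + dx])
  })
  matrix(apply(stack, 1, stats::median), ny, nx)
}

# 0-based pixel coordinates whose centres lie within d/2 of (x, y)
disc_pixels <- function(x, y, diameter, dim_img) {
  r <- diameter / 2
  xs <- max(0, floor(x - r)):min(dim_img[2] - 1, ceiling(x + r))
  ys <- max(0, floor(y - r)):min(dim_img[1] - 1, ceiling(y + r))
  g <- expand.grid(x = xs, y = ys)
  g[(g$x - x)^2 + (g$y - y)^2 <= r^2, , drop = FALSE]
}

#' Background-corrected integrated spot intensity (concentric-ROI scheme)
#'
#' Integrates the raw counts over an inner disc (default 8 px diameter)
#' centred on the spot, estimates the local background from the surrounding
#' annulus out to an outer disc (default 10 px diameter), scales that
#' background to the inner-disc pixel area, and subtracts:
#'
#'   corrected = raw_inner - (raw_outer - raw_inner) * A_in / (A_out - A_in)
#'
#' where the A are pixel counts of the actual disc masks (a pixel belongs to
#' a disc when its centre lies within the disc radius of the centroid). On a
#' flat background the correction is exact; a locally linear ramp cancels to
#' first order because the annulus mean matches the ramp at the centroid.
#' Corrected intensities may be negative on pure noise and are retained.
#'
#' @param image Numeric matrix (for stacks, pass an average-intensity
#'   projection, e.g. from [average_projection()]).
#' @param centroid Numeric `c(x, y)` in 0-based pixel coordinates.
#' @param inner_diameter_px,outer_diameter_px Disc diameters, pixels.
#' @return A one-row data frame: `x_px`, `y_px`, `raw_inner`, `raw_outer`,
#'   `area_inner`, `area_outer`, `corrected_intensity`, `valid` (FALSE when
#'   the outer disc is clipped by the image border, in which case the
#'   intensity is NA and the measurement must be excluded from summaries).
#' @export
measure_corrected_intensity <- function(image, centroid,
                                        inner_diameter_px = 8,
                                        outer_diameter_px = 10) {
  stopifnot(is.matrix(image), length(centroid) == 2,
            outer_diameter_px > inner_diameter_px)
  x <- centroid[1]; y <- centroid[2]
  r_out <- outer_diameter_px / 2
  valid <- x - r_out >= -0.5 && x + r_out <= ncol(image) - 0.5 &&
    y - r_out >= -0.5 && y + r_out <= nrow(image) - 0.5
  if (!valid) {
    return(data.frame(x_px = x, y_px = y, raw_inner = NA_real_,
                      raw_outer = NA_real_, area_inner = NA_integer_,
                      area_outer = NA_integer_,
                      corrected_intensity = NA_real_, valid = FALSE))
  }
  inner <- disc_pixels(x, y, inner_diameter_px, dim(image))
  outer <- disc_pixels(x, y, outer_diameter_px, dim(image))
  raw_inner <- sum(image[cbind(inner$y + 1, inner$x + 1)])
  raw_outer <- sum(image[cbind(outer$y + 1, outer$x + 1)])
  a_in <- nrow(inner); a_out <- nrow(outer)
  corrected <- raw_inner - (raw_outer - raw_inner) * a_in / (a_out - a_in)
  data.frame(x_px = x, y_px = y, raw_inner = raw_inner,
             raw_outer = raw_outer, area_inner = a_in, area_outer = a_out,
             corrected_intensity = corrected, valid = TRUE)
}

#' Measure a table of spots and flag crowded or border-clipped ones
#'
#' Applies [measure_corrected_intensity()] to each centroid and flags spots
#' whose outer disc overlaps another spot's inner disc as `crowded` (their
#' background annulus is contaminated by a neighbour's flux; they should be
#' excluded from calibration summaries).
#'
#' @param image Numeric matrix.
#' @param spots Data frame with `x_px`, `y_px` (e.g. from [detect_spots()]).
#' @inheritParams measure_corrected_intensity
#' @return `spots` augmented with the measurement columns and `crowded`.
#' @export
measure_spots <- function(image, spots, inner_diameter_px = 8,
                          outer_diameter_px = 10) {
  if (!nrow(spots)) {
    out <- cbind(spots, data.frame(raw_inner = numeric(0),
                                   raw_outer = numeric(0),
                                   area_inner = integer(0),
                                   area_outer = integer(0),
                                   corrected_intensity = numeric(0),
                                   valid = logical(0), crowded = logical(0)))
    return(out)
  }
  meas <- do.call(rbind, lapply(seq_len(nrow(spots)), function(k) {
    measure_corrected_intensity(image, c(spots$x_px[k], spots$y_px[k]),
                                inner_diameter_px, outer_diameter_px)
  }))
  out <- cbind(spots[, setdiff(names(spots), c("x_px", "y_px")), drop = FALSE],
               meas)
  d_crowd <- (outer_diameter_px + inner_diameter_px) / 2
  dmat <- as.matrix(stats::dist(cbind(spots$x_px, spots$y_px)))
  diag(dmat) <- Inf
  out$crowded <- apply(dmat < d_crowd, 1, any)
  out
}

#' Average-intensity projection of an image stack
#'
#' @param stack List of matrices (pages of a z-stack or movie).
#' @return The pixelwise mean matrix.
#' @export
average_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  Reduce(`+`, stack) / length(stack)
}

#' Annotate primary-channel spots with secondary-channel signal presence
#'
#' A primary spot is "paired" (e.g. a virion that also carries the tagged
#' motor or envelope marker) when the secondary channel shows signal at its
#' position: either the local signal-to-noise ratio at the centroid —
#' (inner-disc mean - annulus mean) / annulus s.d. — reaches `snr_threshold`,
#' or, when a secondary spot table is given, a secondary detection lies
#' within `pairing_radius`.
#'
#' @param primary_spots Data frame with `x_px`, `y_px`.
#' @param secondary Either the secondary-channel image matrix (same
#'   dimensions as the primary image) or a data frame of secondary spots.
#' @param snr_threshold SNR cut-off (image route). Default 0.4.
#' @param pairing_radius Pairing distance in px (spot-table route).
#' @param primary_image Primary image, used only to validate registration
#'   when `secondary` is an image (optional).
#' @param inner_diameter_px,outer_diameter_px ROI diameters for the SNR.
#' @return `primary_spots` with `snr` (image route) and logical `paired`.
#' @export
pair_channels <- function(primary_spots, secondary, snr_threshold = 0.4,
                          pairing_radius = 4, primary_image = NULL,
                          inner_diameter_px = 8, outer_diameter_px = 10) {
  if (is.matrix(secondary)) {
    if (!is.null(primary_image) &&
        !identical(dim(primary_image), dim(secondary))) {
      stop("channel images are not registered: dimensions differ")
    }
    snr <- vapply(seq_len(nrow(primary_spots)), function(k) {
      x <- primary_spots$x_px[k]; y <- primary_spots$y_px[k]
      r_out <- outer_diameter_px / 2
      if (x - r_out < -0.5 || x + r_out > ncol(secondary) - 0.5 ||
          y - r_out < -0.5 || y + r_out > nrow(secondary) - 0.5) {
        return(NA_real_)
      }
      inner <- disc_pixels(x, y, inner_diameter_px, dim(secondary))
      outer <- disc_pixels(x, y, outer_diameter_px, dim(secondary))
      ann <- outer[!paste(outer$x, outer$y) %in% paste(inner$x, inner$y), ]
      iv <- secondary[cbind(inner$y + 1, inner$x + 1)]
      av <- secondary[cbind(ann$y + 1, ann$x + 1)]
      s <- stats::sd(av)
      if (!is.finite(s) || s == 0) {
        if (mean(iv) > mean(av)) Inf else -Inf
      } else {
        (mean(iv) - mean(av)) / s
      }
    }, numeric(1))
    primary_spots$snr <- snr
    primary_spots$paired <- !is.na(snr) & snr >= snr_threshold
  } else {
    sec <- secondary
    primary_spots$paired <- vapply(seq_len(nrow(primary_spots)), function(k) {
      if (!nrow(sec)) return(FALSE)
      any((sec$x_px - primary_spots$x_px[k])^2 +
          (sec$y_px - primary_spots$y_px[k])^2 <= pairing_radius^2)
    }, logical(1))
  }
  primary_spots$label <- ifelse(primary_spots$paired,
                                "virion_with_signal", "virion_only")
  primary_spots
}
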
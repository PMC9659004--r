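#' Fit the nanocage intensity-to-copy-number calibration curve
#'
#' Fits a through-origin least-squares line to background-corrected spot
#' intensity versus fluorophore copy number for a set of calibration
#' standards (protein nanocages presenting a defined number of fluorescent
#' proteins: typically 24-, 60-, 120- and 180-mers). By default the line is
#' fitted to the per-species mean intensities, as such standard curves are
#' conventionally plotted; `per_spot = TRUE` fits the pooled per-spot values
#' instead.
#'
#' The through-origin slope is `sum(x * ybar_x) / sum(x^2)` over the fitted
#' points; `r_squared` is the uncentred coefficient of determination
#' `1 - SS_res / sum(y^2)` appropriate for a no-intercept fit.
#'
#' @param standards Data frame with columns `copy_number` and `intensity`
#'   (one row per measured spot).
#' @param per_spot Fit pooled per-spot intensities instead of species means.
#' @return An object of class `calibration_curve`: `species` (per-species
#'   `copy_number`, `n_spots`, `mean_intensity`, `sd`), `slope` (counts per
#'   fluorophore), `r_squared`, `per_spot`.
#' @examples
#' std <- data.frame(copy_number = c(24, 60, 120, 180),
#'                   intensity = c(240, 600, 1200, 1800))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, per_spot = FALSE) {
  stopifnot(all(c("copy_number", "intensity") %in% names(standards)),
            nrow(standards) >= 2)
  standards <- standards[is.finite(standards$intensity), , drop = FALSE]
  cn <- sort(unique(standards$copy_number))
  if (length(cn) < 2) {
    stop("calibration requires >= 2 distinct copy numbers (rank deficiency)")
  }
  species <- do.call(rbind, lapply(cn, function(k) {
    v <- standards$intensity[standards$copy_number == k]
    data.frame(copy_number = k, n_spots = length(v),
               mean_intensity = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  if (per_spot) {
    x <- standards$copy_number; y <- standards$intensity
  } else {
    x <- species$copy_number; y <- species$mean_intensity
  }
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  r2 <- 1 - ss_res / sum(y^2)
  structure(list(species = species, slope = slope, r_squared = r2,
                 per_spot = per_spot, n_total = nrow(standards)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Through-origin calibration curve\n")
  cat(sprintf("  slope: %.4g counts per fluorophore (r^2 = %.4f, %s fit)\n",
              x$slope, x$r_squared,
              if (x$per_spot) "per-spot" else "species-mean"))
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(slope = object$slope)
}

#' @export
predict.calibration_curve <- function(object, copy_number, ...) {
  object$slope * copy_number
}

#' @export
plot.calibration_curve <- function(x, ...) {
  sp <- x$species
  graphics::plot(sp$copy_number, sp$mean_intensity,
                 xlab = "fluorophore copy number",
                 ylab = "corrected intensity (counts)",
                 xlim = c(0, max(sp$copy_number) * 1.05),
                 ylim = c(0, max(sp$mean_intensity) * 1.1), pch = 19, ...)
  graphics::abline(0, x$slope)
  invisible(x)
}

#' Convert corrected intensities to fluorophore molecule counts
#'
#' `molecules = intensity / slope`. Negative corrected intensities (possible
#' on noise) map to negative molecule counts — they are not clipped, so that
#' cohort means stay unbiased — and are flagged via the returned attribute
#' `n_negative`.
#'
#' @param corrected_intensity Numeric vector of corrected intensities.
#' @param curve A [fit_calibration()] result.
#' @return Numeric vector of (real-valued) molecule counts.
#' @export
intensity_to_molecules <- function(corrected_intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0")
  out <- corrected_intensity / curve$slope
  attr(out, "n_negative") <- sum(out < 0, na.rm = TRUE)
  out
}

#' Fluorophore molecules to motor complexes
#'
#' Each kinesin-1 motor complex contains two tagged heavy chains, so
#' `complexes = molecules / 2`.
#'
#' @param molecules Numeric vector.
#' @return `molecules / 2`.
#' @export
molecules_to_complexes <- function(molecules) molecules / 2

#' Expression-correction factor between two antibody-intensity cohorts
#'
#' Ratio of cohort mean intensities, `mean(reference) / mean(tagged_line)`:
#' how much stronger the motor signal is in parental (untagged) cells than in
#' the knock-in line whose tagged motor is under-expressed. Motor counts
#' measured in the knock-in line are multiplied by this fold to estimate the
#' counts at native expression.
#'
#' @param reference_intensities Intensities in the reference (parental) line.
#' @param tagged_line_intensities Intensities in the tagged knock-in line.
#' @return The fold difference (unitless, > 0 for valid cohorts).
#' @export
expression_correction_factor <- function(reference_intensities,
                                         tagged_line_intensities) {
  stopifnot(length(reference_intensities) >= 1,
            length(tagged_line_intensities) >= 1)
  m <- mean(tagged_line_intensities)
  if (m <= 0) stop("tagged-line cohort mean must be > 0")
  mean(reference_intensities) / m
}

#' Expression-corrected mean motor-complex count
#'
#' Multiplies a cohort mean complex count by the expression-correction fold
#' and rounds to the nearest integer for reporting.
#'
#' @param mean_complexes Cohort mean number of motor complexes.
#' @param fold Expression-correction factor (> 0).
#' @return Integer number of motor complexes.
#' @examples
#' corrected_mean_complexes(65, 2.14)   # 139
#' corrected_mean_complexes(115, 2.78)  # 320
#' @export
corrected_mean_complexes <- function(mean_complexes, fold) {
  stopifnot(fold > 0)
  round(mean_complexes * fold)
}
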
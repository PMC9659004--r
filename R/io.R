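#' Read a (multi-page) TIFF as a list of matrices
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices (one per page), in the package's
#'   row = y, column = x convention.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
}

#' Write matrices to a (multi-page) TIFF
#'
#' Images are stored as 32-bit floats after scaling counts into [0, 1) by
#' `scale` (the scale is recorded as an attribute on round trip only via
#' the caller; TIFF stores the scaled values).
#'
#' @param images A matrix or list of matrices.
#' @param path Output path.
#' @param scale Divisor applied before writing (counts per unit).
#' @export
write_image_stack <- function(images, path, scale = 65535) {
  if (is.matrix(images)) images <- list(images)
  imgs <- lapply(images, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write an analysis configuration to YAML (and read it back)
#'
#' @param config An [analysis_config()] list.
#' @param path File path (.yaml/.yml or .json by extension).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))] # NULLs fall back to defaults
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, cfg)
}
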
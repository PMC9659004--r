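#' Reconstruct a kymograph along a path
#'
#' Builds the position-versus-time image for a polyline path through a
#' movie: the path is resampled at one column per pixel of arclength, and
#' each column is the transverse mean of `line_width_px` bilinear samples
#' taken perpendicular to the path at that arclength. Rows are frames.
#'
#' @param movie List of frame matrices.
#' @param path Two-column matrix of path vertices in micrometres.
#' @param line_width_px Number of transverse samples averaged per column
#'   (odd; 1 = the path line itself).
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds per frame.
#' @return An object of class `kymograph`: `image` (rows = time, columns =
#'   arclength), `path`, `arclength_um` per column, `line_width_px`,
#'   `pixel_size`, `frame_interval`.
#' @export
build_kymograph <- function(movie, path, line_width_px = 3, pixel_size = 0.1,
                            frame_interval = 1) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2, line_width_px >= 1)
  dims <- dim(movie[[1]])
  # validate vertices first so the error names the offending one
  for (v in seq_len(nrow(path))) {
    xv <- path[v, 1] / pixel_size; yv <- path[v, 2] / pixel_size
    if (xv < 0 || xv > dims[2] - 1 || yv < 0 || yv > dims[1] - 1) {
      stop("path vertex ", v, " (", path[v, 1], ", ", path[v, 2],
           " um) lies outside the image")
    }
  }
  seg_len <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  total <- sum(seg_len)
  n_col <- max(2L, round(total / pixel_size))
  s <- seq(0, total, length.out = n_col)
  cum <- c(0, cumsum(seg_len))
  # sample positions and unit normals along the polyline
  px <- numeric(n_col); py <- numeric(n_col)
  nx_ <- numeric(n_col); ny_ <- numeric(n_col)
  for (k in seq_len(n_col)) {
    i <- max(1L, min(nrow(path) - 1L, findInterval(s[k], cum,
                                                  rightmost.closed = TRUE)))
    t <- (s[k] - cum[i]) / seg_len[i]
    px[k] <- path[i, 1] + t * (path[i + 1, 1] - path[i, 1])
    py[k] <- path[i, 2] + t * (path[i + 1, 2] - path[i, 2])
    ux <- (path[i + 1, 1] - path[i, 1]) / seg_len[i]
    uy <- (path[i + 1, 2] - path[i, 2]) / seg_len[i]
    nx_[k] <- -uy; ny_[k] <- ux
  }
  offsets <- (seq_len(line_width_px) - (line_width_px + 1) / 2) * pixel_size
  img <- matrix(NA_real_, nrow = length(movie), ncol = n_col)
  for (f in seq_along(movie)) {
    fr <- movie[[f]]
    for (k in seq_len(n_col)) {
      sx <- (px[k] + offsets * nx_[k]) / pixel_size
      sy <- (py[k] + offsets * ny_[k]) / pixel_size
      img[f, k] <- mean(bilinear_sample(fr, sx, sy))
    }
  }
  structure(list(image = img, path = path, arclength_um = s,
                 line_width_px = line_width_px, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "kymograph")
}

# bilinear interpolation at 0-based pixel coordinates, clamped to the border
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmax(0, pmin(x, nx - 1)); y <- pmax(0, pmin(y, ny - 1))
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i <- cbind(y0 + 1, x0 + 1)
  img[i] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d columns (%.2f um path, %g s/frame)\n",
              nrow(x$image), ncol(x$image), max(x$arclength_um),
              x$frame_interval))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$arclength_um,
                  (seq_len(nrow(x$image)) - 1) * x$frame_interval,
                  t(x$image)[, rev(seq_len(nrow(x$image))), drop = FALSE],
                  xlab = "position along path (um)", ylab = "time (s)",
                  col = grDevices::gray.colors(256), ...)
  invisible(x)
}

#' Extract constant-velocity runs from along-path position traces
#'
#' Splits each along-path position trace into maximal segments in which the
#' instantaneous along-path speed (3-frame moving average) exceeds
#' `speed_threshold` for at least `min_duration`. Per-run velocity is the
#' least-squares slope of position versus time over the segment; run length
#' is the absolute net position change. When the trace's microtubule length
#' is supplied, runs ending within `end_tolerance` of either tip are marked
#' `reached_end` (a virion that stops at the tip ends its run at arrival:
#' the stationary tail is not part of the run).
#'
#' @param traces List of data frames (`t_s`, `s_um`), or one data frame;
#'   each the arclength position of one virion along its microtubule, e.g.
#'   truth positions from [make_invitro_movie()] or tracked centroids
#'   projected on a path. Optional columns `run_id` and `mt_id` are carried
#'   through.
#' @param frame_interval Seconds per sample.
#' @param min_duration Minimum run duration, seconds.
#' @param speed_threshold Minimum smoothed speed, micrometres per second.
#' @param smooth_frames Moving-average width for the speed trace.
#' @param mt_length_um Optional microtubule length (per trace, recycled) for
#'   end-fate calls.
#' @param end_tolerance Distance from the tip counted as "reached", um.
#' @return Data frame of runs: `trace`, `run_id`, `mt_id`,
#'   `velocity_um_s` (absolute), `signed_slope_um_s`, `run_length_um`,
#'   `start_s`, `end_s`, `end_fate`
#'   (`reached_end` / `not_reached` / `not_discernible`).
#' @export
extract_runs <- function(traces, frame_interval = 1, min_duration = 3,
                         speed_threshold = 0.1, smooth_frames = 3,
                         mt_length_um = NULL, end_tolerance = 0.5) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (!is.null(mt_length_um)) {
    mt_length_um <- rep_len(mt_length_um, length(traces))
  }
  runs <- list()
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    n <- nrow(tr)
    if (n < 2 || (n - 1) * frame_interval < min_duration) next
    spd <- abs(diff(tr$s_um)) / diff(tr$t_s)
    if (smooth_frames > 1 && length(spd) >= smooth_frames) {
      spd <- as.numeric(stats::filter(spd,
        rep(1 / smooth_frames, smooth_frames), sides = 2))
      # fill filter NAs at the ends with the nearest smoothed value
      na_idx <- which(is.na(spd)); ok_idx <- which(!is.na(spd))
      for (ii in na_idx) {
        spd[ii] <- spd[ok_idx[which.min(abs(ok_idx - ii))]]
      }
    }
    raw_spd <- abs(diff(tr$s_um)) / diff(tr$t_s)
    moving <- spd > speed_threshold
    r <- rle(moving)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      i0 <- starts[k]; i1 <- ends[k] + 1L # steps k..k+1 span points
      # smoothing can leak stationary boundary frames into the segment;
      # trim steps whose raw speed does not clear the threshold
      while (i1 - 1L > i0 && raw_spd[i1 - 1L] <= speed_threshold) i1 <- i1 - 1L
      while (i0 < i1 - 1L && raw_spd[i0] <= speed_threshold) i0 <- i0 + 1L
      dur <- tr$t_s[i1] - tr$t_s[i0]
      if (dur < min_duration) next
      tt <- tr$t_s[i0:i1]; ss <- tr$s_um[i0:i1]
      slope <- stats::coef(stats::lm.fit(cbind(1, tt), ss))[2]
      end_fate <- "not_discernible"
      if (!is.null(mt_length_um)) {
        end_pos <- ss[length(ss)]
        end_fate <- if (min(end_pos, mt_length_um[ti] - end_pos) <=
                        end_tolerance) "reached_end" else "not_reached"
      }
      runs[[length(runs) + 1L]] <- data.frame(
        trace = ti,
        run_id = if (!is.null(tr$run_id)) tr$run_id[1] else ti,
        mt_id = if (!is.null(tr$mt_id)) tr$mt_id[1] else NA,
        velocity_um_s = abs(slope), signed_slope_um_s = slope,
        run_length_um = abs(ss[length(ss)] - ss[1]),
        start_s = tr$t_s[i0], end_s = tr$t_s[i1], end_fate = end_fate)
    }
  }
  if (!length(runs)) {
    return(data.frame(trace = integer(0), run_id = integer(0),
                      mt_id = integer(0), velocity_um_s = numeric(0),
                      signed_slope_um_s = numeric(0),
                      run_length_um = numeric(0), start_s = numeric(0),
                      end_s = numeric(0), end_fate = character(0)))
  }
  do.call(rbind, runs)
}

#' Normalised virion motility rate
#'
#' Motile virions per minute of imaging per millimetre of microtubule in the
#' field of view: `n / (minutes * mm)`.
#'
#' @param n_motile_runs Number of motile virions detected.
#' @param imaging_minutes Imaging duration, minutes (> 0).
#' @param total_mt_length_mm Summed microtubule length, millimetres (> 0).
#' @return Rate in virions per minute per millimetre.
#' @examples
#' motility_rate(10, 5, 2)  # 1.0
#' @export
motility_rate <- function(n_motile_runs, imaging_minutes,
                          total_mt_length_mm) {
  stopifnot(imaging_minutes > 0, total_mt_length_mm > 0)
  n_motile_runs / (imaging_minutes * total_mt_length_mm)
}

#' Summarise in vitro runs: velocity, run length, directionality, end fate
#'
#' Direction is scored against microtubule polarity: a positive along-path
#' slope means travel from the path origin toward its far end, which is
#' plus-end-directed when the microtubule's plus end is at the far end.
#' Without a polarity map all directions are `unknown` and the plus-end
#' percentage is reported over zero discernible runs (NaN).
#'
#' @param runs Data frame from [extract_runs()].
#' @param mt_polarity_map Optional data frame (`mt_id`, `polarity` with
#'   values `"plus_at_end"` / `"minus_at_end"`).
#' @return List with `n_runs`, `mean_velocity`, `sd_velocity`,
#'   `mean_run_length`, `sd_run_length`, `percent_plus_end`,
#'   `percent_reached_end`, `percent_not_reached`,
#'   `percent_not_discernible`, and the annotated `runs`.
#' @export
summarize_runs <- function(runs, mt_polarity_map = NULL) {
  if (!nrow(runs)) {
    return(list(n_runs = 0L, mean_velocity = NA_real_, sd_velocity = NA_real_,
                mean_run_length = NA_real_, sd_run_length = NA_real_,
                percent_plus_end = NA_real_, percent_reached_end = NA_real_,
                percent_not_reached = NA_real_,
                percent_not_discernible = NA_real_, runs = runs))
  }
  if (!is.null(mt_polarity_map)) {
    pol <- mt_polarity_map$polarity[match(runs$mt_id, mt_polarity_map$mt_id)]
    runs$direction <- ifelse(is.na(pol), "unknown",
      ifelse((runs$signed_slope_um_s > 0) == (pol == "plus_at_end"),
             "plus", "minus"))
  } else {
    runs$direction <- "unknown"
  }
  known <- runs$direction != "unknown"
  list(
    n_runs = nrow(runs),
    mean_velocity = mean(runs$velocity_um_s),
    sd_velocity = stats::sd(runs$velocity_um_s),
    mean_run_length = mean(runs$run_length_um),
    sd_run_length = stats::sd(runs$run_length_um),
    percent_plus_end = if (any(known)) {
      100 * mean(runs$direction[known] == "plus")
    } else NaN,
    percent_reached_end = 100 * mean(runs$end_fate == "reached_end"),
    percent_not_reached = 100 * mean(runs$end_fate == "not_reached"),
    percent_not_discernible = 100 * mean(runs$end_fate == "not_discernible"),
    runs = runs
  )
}
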
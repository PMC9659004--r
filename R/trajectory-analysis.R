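#' Link per-frame detections into tracks (simple LAP tracker)
#'
#' Two-pass linear-assignment linking in the style used for virion tracking:
#' (1) frame-to-frame assignment minimising total squared displacement among
#' candidate pairs closer than `max_link`, with an alternative "no link" cost
#' of `max_link^2`; (2) a gap-closing pass that reconnects track ends to
#' track starts separated by at most `max_gap` frames and by at most
#' `max_link * sqrt(gap)` in space (diffusive scaling of the search radius).
#' Gap-closed frames receive linearly interpolated positions and are marked
#' `interpolated` so they can be excluded from mean-squared-displacement
#' fits.
#'
#' @param detections Data frame with columns `frame` (integer), `x_um`,
#'   `y_um`, and optionally `id` and `quality`.
#' @param max_link Maximum frame-to-frame linking distance, micrometres.
#' @param max_gap Maximum number of missing frames bridged by gap closing.
#' @param frame_interval Seconds per frame (used to timestamp points).
#' @return An object of class `track_set`: a list with `tracks` (list of
#'   data frames: `frame`, `t_s`, `x_um`, `y_um`, `interpolated`,
#'   `detection_id`) and the linking parameters.
#' @export
link_spots <- function(detections, max_link = 0.8, max_gap = 5,
                       frame_interval = 0.1) {
  req <- c("frame", "x_um", "y_um")
  if (!all(req %in% names(detections))) {
    stop("detections must carry columns: ", paste(req, collapse = ", "))
  }
  det <- detections
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  # active track bookkeeping: list of integer vectors of detection rows
  tracks <- list()
  open_idx <- integer(0)     # indices into `tracks` still extendable
  open_frame <- integer(0)   # last frame of each open track
  prev_rows <- integer(0)    # detection row of each open track's last point
  for (f in frames) {
    rows <- det$.row[det$frame == f]
    if (!length(open_idx)) {
      for (r in rows) {
        tracks[[length(tracks) + 1L]] <- r
        open_idx <- c(open_idx, length(tracks))
        open_frame <- c(open_frame, f)
        prev_rows <- c(prev_rows, r)
      }
      next
    }
    # only tracks whose last point is in the immediately previous frame link
    # here; older ends wait for the gap-closing pass
    curr <- open_frame == f - 1L
    link_to <- rep(NA_integer_, length(rows))
    if (any(curr) && length(rows)) {
      a <- prev_rows[curr]
      m <- lap_link(det$x_um[a], det$y_um[a],
                    det$x_um[rows], det$y_um[rows], max_link)
      ids_curr <- which(curr)
      for (k in seq_along(a)) {
        if (!is.na(m[k])) {
          ti <- open_idx[ids_curr[k]]
          tracks[[ti]] <- c(tracks[[ti]], rows[m[k]])
          open_frame[ids_curr[k]] <- f
          prev_rows[ids_curr[k]] <- rows[m[k]]
          link_to[m[k]] <- ti
        }
      }
    }
    for (j in seq_along(rows)) {
      if (is.na(link_to[j])) {
        tracks[[length(tracks) + 1L]] <- rows[j]
        open_idx <- c(open_idx, length(tracks))
        open_frame <- c(open_frame, f)
        prev_rows <- c(prev_rows, rows[j])
      }
    }
  }

  # gap closing: ends -> starts with 2..max_gap+1 frame difference
  if (max_gap > 0 && length(tracks) > 1) {
    repeat {
      ends <- t(vapply(tracks, function(tr) {
        r <- tr[length(tr)]
        c(det$frame[r], det$x_um[r], det$y_um[r])
      }, numeric(3)))
      starts <- t(vapply(tracks, function(tr) {
        r <- tr[1]
        c(det$frame[r], det$x_um[r], det$y_um[r])
      }, numeric(3)))
      nt <- length(tracks)
      cand <- NULL
      for (i in seq_len(nt)) {
        gap <- starts[, 1] - ends[i, 1] - 1
        d <- sqrt((starts[, 2] - ends[i, 2])^2 + (starts[, 3] - ends[i, 3])^2)
        ok <- which(gap >= 1 & gap <= max_gap &
                      d <= max_link * sqrt(pmax(1, gap + 1)))
        ok <- setdiff(ok, i)
        if (length(ok)) {
          cand <- rbind(cand, cbind(i, ok, d[ok]^2))
        }
      }
      if (is.null(cand)) break
      # greedy-optimal: solve assignment on the candidate bipartite graph
      is_ <- sort(unique(cand[, 1])); js <- sort(unique(cand[, 2]))
      ml <- lap_link_pairs(cand, is_, js)
      if (!nrow(ml)) break
      # merge highest-index targets first so indices stay valid
      ml <- ml[order(-ml[, 2]), , drop = FALSE]
      drop <- integer(0)
      for (k in seq_len(nrow(ml))) {
        i <- ml[k, 1]; j <- ml[k, 2]
        if (i %in% drop || j %in% drop) next
        tracks[[i]] <- c(tracks[[i]], tracks[[j]])
        drop <- c(drop, j)
      }
      tracks <- tracks[-drop]
    }
  }

  out <- lapply(tracks, function(rws) {
    rws <- rws[order(det$frame[match(rws, det$.row)])]
    d <- det[match(rws, det$.row), c("frame", "x_um", "y_um"), drop = FALSE]
    full <- data.frame(frame = seq(min(d$frame), max(d$frame)))
    full <- merge(full, cbind(d, detection_id = rws), by = "frame",
                  all.x = TRUE)
    miss <- is.na(full$x_um)
    if (any(miss)) {
      full$x_um <- stats::approx(full$frame[!miss], full$x_um[!miss],
                                 xout = full$frame)$y
      full$y_um <- stats::approx(full$frame[!miss], full$y_um[!miss],
                                 xout = full$frame)$y
    }
    full$interpolated <- miss
    full$t_s <- (full$frame - 1) * frame_interval
    full[, c("frame", "t_s", "x_um", "y_um", "interpolated", "detection_id")]
  })
  structure(list(tracks = out, max_link = max_link, max_gap = max_gap,
                 frame_interval = frame_interval),
            class = "track_set")
}

# assignment restricted to candidate (end, start, cost) triples
lap_link_pairs <- function(cand, is_, js) {
  BIG <- 1e12
  n <- length(is_); m <- length(js)
  cmat <- matrix(BIG, n, m)
  for (k in seq_len(nrow(cand))) {
    cmat[match(cand[k, 1], is_), match(cand[k, 2], js)] <- cand[k, 3]
  }
  sz <- n + m
  full <- matrix(0, sz, sz)
  full[seq_len(n), seq_len(m)] <- cmat
  full[seq_len(n), m + seq_len(n)] <- BIG
  full[n + seq_len(m), seq_len(m)] <- BIG
  alt <- max(cand[, 3]) + 1
  for (i in seq_len(n)) full[i, m + i] <- alt
  for (j in seq_len(m)) full[n + j, j] <- alt
  asg <- solve_assignment(full)
  out <- NULL
  for (i in seq_len(n)) {
    j <- asg[i]
    if (j <= m && cmat[i, j] < BIG) out <- rbind(out, c(is_[i], js[j]))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(x$tracks)
  len <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("Track set: %d tracks (%d-%d points, median %g)\n",
              n, if (n) min(len) else 0, if (n) max(len) else 0,
              if (n) stats::median(len) else 0))
  invisible(x)
}

net_displacement <- function(track) {
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Filter tracks by net start-to-end displacement
#'
#' Keeps tracks whose net displacement strictly exceeds
#' `min_total_displacement` (default 1 um), removing stationary background
#' particles before motion-state analysis.
#'
#' @param tracks A `track_set` from [link_spots()] or a list of track data
#'   frames.
#' @param min_total_displacement Threshold in micrometres.
#' @return The filtered object of the same type.
#' @export
filter_by_displacement <- function(tracks, min_total_displacement = 1) {
  lst <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  # a non-positive threshold disables the filter entirely
  keep <- vapply(lst, function(tr) min_total_displacement <= 0 ||
                   net_displacement(tr) > min_total_displacement, logical(1))
  if (inherits(tracks, "track_set")) {
    tracks$tracks <- lst[keep]
    tracks
  } else {
    lst[keep]
  }
}

# windowed MSD log-log slope (alpha) and straightness around each point
track_point_features <- function(track, window, max_lag) {
  n <- nrow(track)
  half <- floor(window / 2)
  use <- if (!is.null(track$interpolated)) !track$interpolated else rep(TRUE, n)
  alpha <- numeric(n); straight <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    x <- track$x_um[lo:hi]; y <- track$y_um[lo:hi]
    ok <- use[lo:hi]
    m <- length(x)
    lags <- seq_len(min(max_lag, m - 1))
    msd <- vapply(lags, function(L) {
      a <- 1:(m - L)
      b <- a + L
      sel <- ok[a] & ok[b]
      if (!any(sel)) return(NA_real_)
      mean((x[b[sel]] - x[a[sel]])^2 + (y[b[sel]] - y[a[sel]])^2)
    }, numeric(1))
    good <- is.finite(msd) & msd > 0
    alpha[i] <- if (sum(good) >= 2) {
      stats::coef(stats::lm.fit(cbind(1, log(lags[good])),
                                log(msd[good])))[2]
    } else NA_real_
    path <- sum(sqrt(diff(x)^2 + diff(y)^2))
    net <- sqrt((x[m] - x[1])^2 + (y[m] - y[1])^2)
    straight[i] <- if (path > 0) net / path else 0
  }
  data.frame(alpha = alpha, straightness = straight)
}

# MSD curve of points lo..hi at the given lags, skipping pairs that touch
# gap-interpolated points
segment_msd <- function(track, lo, hi, lags) {
  x <- track$x_um[lo:hi]; y <- track$y_um[lo:hi]
  ok <- if (!is.null(track$interpolated)) {
    !track$interpolated[lo:hi]
  } else {
    rep(TRUE, hi - lo + 1)
  }
  m <- length(x)
  vapply(lags, function(L) {
    a <- seq_len(m - L); b <- a + L
    sel <- ok[a] & ok[b]
    if (!any(sel)) return(NA_real_)
    mean((x[b[sel]] - x[a[sel]])^2 + (y[b[sel]] - y[a[sel]])^2)
  }, numeric(1))
}

loglog_slope <- function(lags, msd) {
  good <- is.finite(msd) & msd > 0
  if (sum(good) < 2) return(NA_real_)
  stats::coef(stats::lm.fit(cbind(1, log(lags[good])), log(msd[good])))[[2]]
}

# Label one non-active stretch from whole-stretch statistics.  Two
# features, both corrected for the localization-noise floor (estimated by
# linear back-extrapolation of the MSD to lag 0):
#   * escape ratio: squared extent of the point cloud over n times the
#     one-lag MSD — ~O(1) scale-free; free diffusion escapes (>1), motion
#     confined to a disc cannot (<1);
#   * alpha: log-log MSD slope over lags 1..min(n/5, 40) — ~1 for normal
#     diffusion, 2H < 1 for fractional-Brownian subdiffusion.
classify_passive_segment <- function(track, lo, hi, th) {
  n <- hi - lo + 1
  max_lag <- max(2L, min(floor(n / 5), 40L))
  lags <- seq_len(max_lag)
  msd <- segment_msd(track, lo, hi, lags)
  if (!all(is.finite(msd)) || msd[1] <= 0) return("normal_diffusion")
  # noise floor = intercept of a short-lag linear fit, clamped to [0, msd(1)]
  k <- seq_len(min(4L, max_lag))
  offset <- if (length(k) >= 2) {
    min(msd[1], max(0, stats::coef(stats::lm.fit(cbind(1, k), msd[k]))[[1]]))
  } else 0
  mc <- pmax(msd - offset, .Machine$double.eps)
  x <- track$x_um[lo:hi]; y <- track$y_um[lo:hi]
  diam2 <- (max(x) - min(x))^2 + (max(y) - min(y))^2
  esc <- if (mc[1] > 1e-12) diam2 / (n * mc[1]) else 0
  alpha <- loglog_slope(lags, mc)
  if (is.na(alpha)) return("normal_diffusion")
  if (esc <= th$esc_confined || alpha <= th$alpha_confined) {
    "confined"
  } else if (alpha < th$alpha_subdiffusion) {
    "subdiffusion"
  } else {
    "normal_diffusion"
  }
}

#' Segment a track into motion states
#'
#' Two-scale classification. First, every point is scored active or not from
#' sliding-window features: the log-log MSD slope `alpha` over lags
#' `1..floor(window/3)` and the window straightness (net over path length);
#' a point is active when `alpha >= alpha_active` and straightness
#' `>= straightness_active`. Active/passive stretches shorter than
#' `min_segment` frames are absorbed into their longer neighbour, so the
#' returned segments tile the track exactly. Second, each maximal passive
#' stretch is labelled as a whole from noise-floor-corrected whole-stretch
#' statistics: a scale-free escape ratio (squared cloud extent over `n`
#' times the one-lag MSD; free diffusion escapes, confined motion cannot)
#' calls `confined` when `<= esc_confined`, and otherwise the MSD log-log
#' slope over lags `1..min(n/5, 40)` calls `subdiffusion` below
#' `alpha_subdiffusion` and `normal_diffusion` above it. Confinement and
#' anomalous diffusion are properties of a trajectory stretch, not of a
#' single 1-2 s window, which is why they are scored at segment scale while
#' active transport — locally evident as straight, superlinear motion — is
#' scored per point.
#'
#' @param track Track data frame (`frame`, `t_s`, `x_um`, `y_um`, optional
#'   `interpolated` — interpolated points are excluded from MSD fits).
#' @param window Sliding window length in frames for the active score.
#' @param thresholds Named list overriding `alpha_active` (1.5),
#'   `alpha_confined` (0.4), `alpha_subdiffusion` (0.8),
#'   `straightness_active` (0.6), `min_segment` (5), `esc_confined` (1.0).
#' @return Data frame of segments: `start_frame`, `end_frame`, `n_frames`,
#'   `state`, and for active segments `velocity_um_s` (net displacement over
#'   duration) and `run_length_um` (net displacement). The per-point state
#'   vector is attached as attribute `point_states`.
#' @export
classify_segments <- function(track, window = 15, thresholds = list()) {
  th <- utils::modifyList(list(alpha_active = 1.3, alpha_confined = 0.4,
                               alpha_subdiffusion = 0.8,
                               straightness_active = 0.6, min_segment = 5,
                               esc_confined = 1.0),
                          thresholds)
  n <- nrow(track)
  max_lag <- max(1L, floor(window / 3))
  feat <- track_point_features(track, min(window, n), max_lag)
  active <- !is.na(feat$alpha) & feat$alpha >= th$alpha_active &
    feat$straightness >= th$straightness_active
  if (n < window) active[] <- stats::median(active) > 0
  segs <- rle(ifelse(active, "active", "passive"))
  # absorb short stretches into the longer neighbour until stable
  repeat {
    if (length(segs$lengths) <= 1) break
    short <- which(segs$lengths < th$min_segment)
    if (!length(short)) break
    k <- short[which.min(segs$lengths[short])]
    left <- if (k > 1) segs$lengths[k - 1] else -1
    right <- if (k < length(segs$lengths)) segs$lengths[k + 1] else -1
    into <- if (left >= right) k - 1 else k + 1
    segs$values[k] <- segs$values[into]
    segs <- rle(inverse.rle(segs))
  }
  ends <- cumsum(segs$lengths)
  starts <- ends - segs$lengths + 1
  for (k in seq_along(segs$values)) {
    if (segs$values[k] == "passive") {
      segs$values[k] <- classify_passive_segment(track, starts[k], ends[k],
                                                 th)
    }
  }
  state <- inverse.rle(segs)
  segs <- rle(state) # adjacent passive stretches may share a label now
  ends <- cumsum(segs$lengths)
  starts <- ends - segs$lengths + 1
  out <- data.frame(start_frame = track$frame[starts],
                    end_frame = track$frame[ends],
                    n_frames = segs$lengths, state = segs$values,
                    velocity_um_s = NA_real_, run_length_um = NA_real_)
  for (k in seq_len(nrow(out))) {
    if (out$state[k] == "active") {
      i0 <- starts[k]; i1 <- ends[k]
      net <- sqrt((track$x_um[i1] - track$x_um[i0])^2 +
                  (track$y_um[i1] - track$y_um[i0])^2)
      dur <- track$t_s[i1] - track$t_s[i0]
      out$run_length_um[k] <- net
      out$velocity_um_s[k] <- if (dur > 0) net / dur else NA_real_
    }
  }
  attr(out, "point_states") <- state
  out
}

#' Summary statistics of active-transport segments
#'
#' @param segments Data frame(s) from [classify_segments()] (a single data
#'   frame or a list, e.g. one per track).
#' @return A list with `velocities_um_s`, `run_lengths_um`,
#'   `mean_velocity`, `sd_velocity`, `mean_run_length`, `sd_run_length`,
#'   `n_runs`, and `status` (`"ok"` or `"no active runs"`).
#' @export
active_transport_stats <- function(segments) {
  if (is.data.frame(segments)) segments <- list(segments)
  seg <- do.call(rbind, segments)
  act <- seg[seg$state == "active" & is.finite(seg$velocity_um_s), ,
             drop = FALSE]
  if (!nrow(act)) {
    return(list(velocities_um_s = numeric(0), run_lengths_um = numeric(0),
                mean_velocity = NA_real_, sd_velocity = NA_real_,
                mean_run_length = NA_real_, sd_run_length = NA_real_,
                n_runs = 0L, status = "no active runs"))
  }
  list(velocities_um_s = act$velocity_um_s,
       run_lengths_um = act$run_length_um,
       mean_velocity = mean(act$velocity_um_s),
       sd_velocity = stats::sd(act$velocity_um_s),
       mean_run_length = mean(act$run_length_um),
       sd_run_length = stats::sd(act$run_length_um),
       n_runs = nrow(act), status = "ok")
}

#' Count motile tracks (net displacement rule)
#'
#' A track counts as motile when its net displacement within the imaging
#' window strictly exceeds `min_displacement` (default: travelled more than
#' 3 um within 60 s).
#'
#' @param tracks A `track_set` or list of track data frames.
#' @param min_displacement Micrometres.
#' @param window Imaging window, seconds; only points with
#'   `t_s <= window` (relative to each track's first point) are considered.
#' @return Integer count.
#' @export
count_motile <- function(tracks, min_displacement = 3, window = 60) {
  lst <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  sum(vapply(lst, function(tr) {
    sel <- tr$t_s - tr$t_s[1] <= window
    sub <- tr[sel, , drop = FALSE]
    net_displacement(sub) > min_displacement
  }, logical(1)))
}
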
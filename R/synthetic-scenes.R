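#' Simulate a field of diffraction-limited spots with known copy numbers
#'
#' Renders one image per channel containing point emitters whose expected
#' integrated flux above background is `copy_number * photons_per_fluorophore`.
#' This emulates the nanocage calibration standards (defined 24/60/120/180
#' fluorophore copies per particle) and virions carrying a known number of
#' fluorescently tagged motors, over a noisy, possibly sloped background.
#'
#' The PSF is an integrated 2-D Gaussian (flux is exact on the pixel grid);
#' noise is Poisson shot noise on photons followed by Gaussian read noise and
#' a constant camera offset. With `optics$shot_noise = FALSE` and
#' `read_noise_sd = 0` the rendered image is the exact expectation.
#'
#' @param species_spec Data frame with columns `copy_number`, `n_spots` and
#'   optionally `channel` (default 1): one row per species to render.
#' @param optics An [optics_model()].
#' @param field_size Image size in pixels, `c(ny, nx)` (a single number is
#'   used for both).
#' @param min_separation Minimum pairwise centre distance between spots, px.
#' @param seed Integer seed; fixed seeds give bit-identical scenes.
#'
#' @return A list with `images` (named list of matrices, one per channel) and
#'   `truth` (data frame: `id`, `channel`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `copy_number`), plus the `optics` used.
#' @examples
#' op <- optics_model(shot_noise = FALSE, read_noise_sd = 0,
#'                    background_level = 0)
#' sc <- make_spot_scene(data.frame(copy_number = 60, n_spots = 1),
#'                       op, field_size = 32, min_separation = 5, seed = 1)
#' sum(sc$images[[1]]) - 32^2 * op$camera_offset  # 60 * 100 photons
#' @export
make_spot_scene <- function(species_spec, optics, field_size = 256,
                            min_separation = 12, seed = 1) {
  stopifnot(inherits(optics, "optics_model"),
            all(c("copy_number", "n_spots") %in% names(species_spec)))
  if (is.null(species_spec$channel)) species_spec$channel <- 1L
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  set.seed(seed)

  n_total <- sum(species_spec$n_spots)
  margin <- ceiling(6 * optics$psf_sigma) + 1
  truth <- data.frame(
    id = seq_len(n_total),
    channel = rep(species_spec$channel, species_spec$n_spots),
    copy_number = rep(species_spec$copy_number, species_spec$n_spots)
  )
  pos <- place_points(n_total, field_size, min_separation, margin = margin)
  truth$x_px <- pos[, "x"]
  truth$y_px <- pos[, "y"]
  truth$x_um <- truth$x_px * optics$pixel_size
  truth$y_um <- truth$y_px * optics$pixel_size

  images <- list()
  for (ch in sort(unique(truth$channel))) {
    sel <- truth[truth$channel == ch, , drop = FALSE]
    spots <- data.frame(x_px = sel$x_px, y_px = sel$y_px,
                        flux = sel$copy_number * optics$photons_per_fluorophore)
    expected <- expected_photon_image(field_size, optics, spots)
    images[[as.character(ch)]] <- apply_camera(expected, optics)
  }
  list(images = images, truth = truth, optics = optics)
}

#' Simulate an in vitro microtubule transport movie
#'
#' Renders a time-lapse in which virion spots translocate at constant planned
#' speeds along straight microtubules, emulating a reconstituted motility
#' assay on surface-attached GMPCPP-stabilised microtubules imaged at ~1
#' frame/s. A virion whose run reaches the microtubule tip either remains
#' stationary there (`end_behaviour = "reach_end_stop"`, as virions in such
#' assays often stall at the end rather than detaching) or disappears
#' (`"detach"`).
#'
#' @param mt_layout Data frame of microtubules: `mt_id`, `x0_um`, `y0_um`,
#'   `x1_um`, `y1_um`, and `polarity` (`"plus_at_end"` if the plus end is at
#'   (x1, y1), `"minus_at_end"` otherwise).
#' @param run_plan Data frame of runs: `run_id`, `mt_id`, `speed_um_s`,
#'   `start_time_s`, `duration_s`, `start_offset_um` (initial arclength from
#'   the (x0, y0) end), `direction` (`"plus"` or `"minus"`, relative to
#'   microtubule polarity), `end_behaviour` (`"reach_end_stop"` or
#'   `"detach"`), and optionally `flux_photons` (default 2e4).
#' @param optics An [optics_model()].
#' @param frame_interval Time between frames, seconds.
#' @param n_frames Number of frames.
#' @param field_size Image size in pixels `c(ny, nx)` or a single number.
#' @param localization_noise_sd Isotropic Gaussian jitter applied to each
#'   rendered spot position per frame, micrometres (emulates residual
#'   localization error); 0 for none.
#' @param seed Integer seed.
#'
#' @return A list with `movie` (list of frame matrices), `truth` (the run
#'   plan augmented with realised start/end arclengths and net displacement),
#'   `positions` (per-frame true positions: `run_id`, `frame`, `t_s`, `s_um`
#'   arclength, `x_um`, `y_um`, `visible`), `mt_layout`, `optics`,
#'   `frame_interval`.
#' @export
make_invitro_movie <- function(mt_layout, run_plan, optics,
                               frame_interval = 1, n_frames = 20,
                               field_size = 128,
                               localization_noise_sd = 0, seed = 1) {
  stopifnot(inherits(optics, "optics_model"), frame_interval > 0, n_frames >= 1)
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  if (is.null(run_plan$flux_photons)) run_plan$flux_photons <- 2e4
  if (is.null(run_plan$start_offset_um)) run_plan$start_offset_um <- 0
  set.seed(seed)

  mt_layout$length_um <- sqrt((mt_layout$x1_um - mt_layout$x0_um)^2 +
                              (mt_layout$y1_um - mt_layout$y0_um)^2)
  # travel direction along arclength: +1 moves from (x0,y0) toward (x1,y1)
  run_plan$sgn <- vapply(seq_len(nrow(run_plan)), function(k) {
    mt <- mt_layout[mt_layout$mt_id == run_plan$mt_id[k], ]
    towards_end <- (mt$polarity == "plus_at_end") == (run_plan$direction[k] == "plus")
    if (towards_end) 1 else -1
  }, numeric(1))

  # validate: runs must fit, or carry an end_behaviour
  for (k in seq_len(nrow(run_plan))) {
    mt <- mt_layout[mt_layout$mt_id == run_plan$mt_id[k], ]
    s_end <- run_plan$start_offset_um[k] +
      run_plan$sgn[k] * run_plan$speed_um_s[k] * run_plan$duration_s[k]
    if ((s_end < 0 || s_end > mt$length_um) &&
        (is.null(run_plan$end_behaviour) ||
         is.na(run_plan$end_behaviour[k]))) {
      stop("run ", run_plan$run_id[k], " exceeds microtubule ", mt$mt_id,
           " (length ", round(mt$length_um, 2),
           " um) and has no end_behaviour")
    }
  }

  times <- (seq_len(n_frames) - 1) * frame_interval
  pos <- do.call(rbind, lapply(seq_len(nrow(run_plan)), function(k) {
    rp <- run_plan[k, ]
    mt <- mt_layout[mt_layout$mt_id == rp$mt_id, ]
    s <- rp$start_offset_um + rp$sgn * rp$speed_um_s *
      pmax(0, pmin(times - rp$start_time_s, rp$duration_s))
    visible <- times >= rp$start_time_s
    hit <- s < 0 | s > mt$length_um
    if (any(hit)) {
      s_clip <- pmax(0, pmin(s, mt$length_um))
      if (identical(rp$end_behaviour, "detach")) {
        visible <- visible & !hit
      }
      s <- s_clip
    }
    ux <- (mt$x1_um - mt$x0_um) / mt$length_um
    uy <- (mt$y1_um - mt$y0_um) / mt$length_um
    data.frame(run_id = rp$run_id, frame = seq_len(n_frames), t_s = times,
               s_um = s, x_um = mt$x0_um + ux * s, y_um = mt$y0_um + uy * s,
               visible = visible)
  }))

  if (localization_noise_sd > 0) {
    pos$x_um <- pos$x_um + stats::rnorm(nrow(pos), 0, localization_noise_sd)
    pos$y_um <- pos$y_um + stats::rnorm(nrow(pos), 0, localization_noise_sd)
  }

  movie <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    p <- pos[pos$frame == f & pos$visible, , drop = FALSE]
    flux <- run_plan$flux_photons[match(p$run_id, run_plan$run_id)]
    spots <- data.frame(x_px = p$x_um / optics$pixel_size,
                        y_px = p$y_um / optics$pixel_size, flux = flux)
    expected <- expected_photon_image(field_size, optics, spots)
    movie[[f]] <- apply_camera(expected, optics)
  }

  truth <- run_plan
  truth$sgn <- NULL
  truth$net_displacement_um <- vapply(run_plan$run_id, function(id) {
    p <- pos[pos$run_id == id, ]
    abs(p$s_um[nrow(p)] - p$s_um[1])
  }, numeric(1))

  list(movie = movie, truth = truth, positions = pos, mt_layout = mt_layout,
       optics = optics, frame_interval = frame_interval)
}

#' Specify one trajectory plan for the motion-state simulator
#'
#' A plan is an ordered list of motion segments, each one of the four states
#' a virion trajectory is segmented into: `"active"` (straight-line transport
#' at speed `v_um_s`), `"normal_diffusion"` (Gaussian random walk with
#' per-axis step variance 2*D*dt), `"subdiffusion"` (fractional Brownian
#' motion with Hurst exponent `hurst` < 0.5), or `"confined"` (random walk
#' reflected inside a disc of radius `radius_um`).
#'
#' @param segments List of segment specs; each a list with `state`,
#'   `duration_s`, and the state's parameter (`v_um_s`, `d_um2_s`,
#'   `d_um2_s` + `hurst`, or `d_um2_s` + `radius_um`).
#' @param dt Frame interval, seconds.
#' @param localization_noise_sd Gaussian localization noise added to the
#'   observed positions, micrometres.
#' @return An object of class `trajectory_plan`.
#' @export
trajectory_plan <- function(segments, dt = 0.1, localization_noise_sd = 0) {
  stopifnot(dt > 0, length(segments) >= 1)
  states <- c("active", "normal_diffusion", "subdiffusion", "confined")
  for (sg in segments) {
    if (!sg$state %in% states) {
      stop("unknown motion state '", sg$state, "'")
    }
    if (is.null(sg$duration_s) || sg$duration_s <= 0) {
      stop("segment durations must be > 0")
    }
    if (sg$state == "active" && (is.null(sg$v_um_s) || sg$v_um_s < 0)) {
      stop("active segments need v_um_s >= 0")
    }
    if (sg$state != "active" && (is.null(sg$d_um2_s) || sg$d_um2_s <= 0)) {
      stop("diffusive segments need d_um2_s > 0")
    }
    if (sg$state == "subdiffusion" &&
        (is.null(sg$hurst) || sg$hurst <= 0 || sg$hurst >= 0.5)) {
      stop("subdiffusion needs 0 < hurst < 0.5")
    }
    if (sg$state == "confined" &&
        (is.null(sg$radius_um) || sg$radius_um <= 0)) {
      stop("confined segments need radius_um > 0")
    }
  }
  structure(list(segments = segments, dt = dt,
                 localization_noise_sd = localization_noise_sd),
            class = "trajectory_plan")
}

# Fractional Gaussian noise by Cholesky factorisation of the increment
# covariance; sigma2 is the one-step increment variance.
fgn_increments <- function(n, hurst, sigma2) {
  if (n == 0L) return(numeric(0))
  k <- 0:(n - 1)
  acov <- sigma2 / 2 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                        abs(k - 1)^(2 * hurst))
  cov <- stats::toeplitz(acov)
  L <- chol(cov)
  as.vector(t(L) %*% stats::rnorm(n))
}

#' Simulate 2-D trajectories with labelled motion states
#'
#' Generates tracks sampled at `1/dt` Hz that alternate through the motion
#' states of their plans, with per-point ground-truth state labels for
#' recovery testing of the motion-state classifier.
#'
#' @param plans A [trajectory_plan()] or list of plans, recycled over tracks.
#' @param n_tracks Number of tracks.
#' @param field_um Track origins are drawn uniformly in a `field_um` x
#'   `field_um` box (large fields keep concurrent tracks well separated for
#'   re-linking tests).
#' @param seed Integer seed.
#' @return A list with `tracks` (list of data frames: `frame`, `t_s`, `x_um`,
#'   `y_um`) and `truth` (data frame: `track_id`, `frame`, `state` — the
#'   noise-free state labels), and `dt`.
#' @export
make_trajectory_set <- function(plans, n_tracks = 1, field_um = 200,
                                seed = 1) {
  if (inherits(plans, "trajectory_plan")) plans <- list(plans)
  set.seed(seed)
  tracks <- vector("list", n_tracks)
  truth <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    plan <- plans[[(i - 1L) %% length(plans) + 1L]]
    dt <- plan$dt
    x <- stats::runif(1, 0, field_um)
    y <- stats::runif(1, 0, field_um)
    xs <- x; ys <- y; states <- character(0)
    # first point carries the first segment's state
    for (sg in plan$segments) {
      n_steps <- max(1L, round(sg$duration_s / dt))
      x0 <- xs[length(xs)]; y0 <- ys[length(ys)]
      if (sg$state == "active") {
        theta <- stats::runif(1, 0, 2 * pi)
        step <- sg$v_um_s * dt
        nx <- x0 + cumsum(rep(step * cos(theta), n_steps))
        nyv <- y0 + cumsum(rep(step * sin(theta), n_steps))
      } else if (sg$state == "normal_diffusion") {
        sd1 <- sqrt(2 * sg$d_um2_s * dt)
        nx <- x0 + cumsum(stats::rnorm(n_steps, 0, sd1))
        nyv <- y0 + cumsum(stats::rnorm(n_steps, 0, sd1))
      } else if (sg$state == "subdiffusion") {
        s2 <- 2 * sg$d_um2_s * dt^(2 * sg$hurst)
        nx <- x0 + cumsum(fgn_increments(n_steps, sg$hurst, s2))
        nyv <- y0 + cumsum(fgn_increments(n_steps, sg$hurst, s2))
      } else { # confined: reflected random walk in a disc about segment start
        sd1 <- sqrt(2 * sg$d_um2_s * dt)
        L <- sg$radius_um
        nx <- numeric(n_steps); nyv <- numeric(n_steps)
        px <- x0; py <- y0
        for (s in seq_len(n_steps)) {
          px2 <- px + stats::rnorm(1, 0, sd1)
          py2 <- py + stats::rnorm(1, 0, sd1)
          r <- sqrt((px2 - x0)^2 + (py2 - y0)^2)
          if (r > L) { # radial reflection at the disc boundary
            scale <- (2 * L - r) / r
            px2 <- x0 + (px2 - x0) * scale
            py2 <- y0 + (py2 - y0) * scale
            r2 <- sqrt((px2 - x0)^2 + (py2 - y0)^2)
            if (r2 > L) { scale <- L / r2
              px2 <- x0 + (px2 - x0) * scale
              py2 <- y0 + (py2 - y0) * scale }
          }
          px <- px2; py <- py2
          nx[s] <- px; nyv[s] <- py
        }
      }
      xs <- c(xs, nx); ys <- c(ys, nyv)
      states <- c(states, rep(sg$state, n_steps))
    }
    states <- c(states[1], states) # first point labelled by first segment
    n_pts <- length(xs)
    obs_x <- xs; obs_y <- ys
    if (plan$localization_noise_sd > 0) {
      obs_x <- obs_x + stats::rnorm(n_pts, 0, plan$localization_noise_sd)
      obs_y <- obs_y + stats::rnorm(n_pts, 0, plan$localization_noise_sd)
    }
    tracks[[i]] <- data.frame(frame = seq_len(n_pts),
                              t_s = (seq_len(n_pts) - 1) * dt,
                              x_um = obs_x, y_um = obs_y)
    truth[[i]] <- data.frame(track_id = i, frame = seq_len(n_pts),
                             state = states)
  }
  list(tracks = tracks, truth = do.call(rbind, truth),
       dt = plans[[1]]$dt)
}

#' Simulate a cell mask with interior and peripheral virion point patterns
#'
#' Rasterizes a simple polygon cell outline into a binary mask and places
#' spots either uniformly or with prescribed interior / peripheral counts,
#' where "peripheral" means within `band_um` of the cell edge (Euclidean
#' distance to the polygon boundary).
#'
#' @param cell_polygon Two-column matrix of polygon vertices in micrometres
#'   (closed implicitly; must be simple).
#' @param spot_placement Either `list(n = k)` for `k` uniform spots, or
#'   `list(n_interior = a, n_peripheral = b)`.
#' @param pixel_size Rasterization pixel size, micrometres per pixel.
#' @param band_um Width of the peripheral band used for truth labels, um.
#' @param seed Integer seed.
#' @return A list with `mask` (logical matrix), `spots` (data frame `x_um`,
#'   `y_um`, `region` truth label), `pixel_size`, `band_um`.
#' @export
make_cell_scene <- function(cell_polygon, spot_placement, pixel_size = 0.1,
                            band_um = 5, seed = 1) {
  cell_polygon <- as.matrix(cell_polygon)
  stopifnot(ncol(cell_polygon) == 2, nrow(cell_polygon) >= 3)
  if (polygon_self_intersects(cell_polygon)) {
    stop("cell_polygon is self-intersecting; a simple closed polygon is required")
  }
  set.seed(seed)
  xr <- range(cell_polygon[, 1]); yr <- range(cell_polygon[, 2])
  nx <- ceiling(xr[2] / pixel_size) + 2
  ny <- ceiling(yr[2] / pixel_size) + 2
  px <- (seq_len(nx) - 1) * pixel_size
  py <- (seq_len(ny) - 1) * pixel_size
  grid <- expand.grid(x = px, y = py)
  inside <- point_in_polygon(grid$x, grid$y, cell_polygon)
  mask <- matrix(inside, nrow = ny, ncol = nx, byrow = TRUE)

  draw_uniform <- function(n, predicate = NULL) {
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      m <- max(100L, 2L * (n - nrow(out)))
      cx <- stats::runif(m, xr[1], xr[2])
      cy <- stats::runif(m, yr[1], yr[2])
      ok <- point_in_polygon(cx, cy, cell_polygon)
      if (!is.null(predicate)) ok <- ok & predicate(cx, cy)
      out <- rbind(out, cbind(cx[ok], cy[ok]))
    }
    out[seq_len(n), , drop = FALSE]
  }

  edge_dist <- function(cx, cy) dist_to_polygon(cx, cy, cell_polygon)

  if (!is.null(spot_placement$n)) {
    n <- spot_placement$n
    pts <- if (n > 0) draw_uniform(n) else matrix(numeric(0), ncol = 2)
  } else {
    a <- spot_placement$n_interior %||% 0
    b <- spot_placement$n_peripheral %||% 0
    pi_ <- if (a > 0) draw_uniform(a, function(x, y) edge_dist(x, y) > band_um)
           else matrix(numeric(0), ncol = 2)
    pp <- if (b > 0) draw_uniform(b, function(x, y) edge_dist(x, y) <= band_um)
          else matrix(numeric(0), ncol = 2)
    pts <- rbind(pi_, pp)
  }
  spots <- if (nrow(pts)) {
    data.frame(x_um = pts[, 1], y_um = pts[, 2],
               region = ifelse(edge_dist(pts[, 1], pts[, 2]) > band_um,
                               "interior", "peripheral"))
  } else {
    data.frame(x_um = numeric(0), y_um = numeric(0), region = character(0))
  }
  list(mask = mask, spots = spots, pixel_size = pixel_size, band_um = band_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# even-odd rule point-in-polygon, vectorised over points
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum Euclidean distance from points to the polygon boundary
dist_to_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmax(0, pmin(1, ((x - ax) * vx + (y - ay) * vy) / len2))
         else 0
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    list(a = poly[i, ], b = poly[j, ])
  }
  inter <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1$a, s1$b, s2$a, s2$b)) return(TRUE)
    }
  }
  FALSE
}
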
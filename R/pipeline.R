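#' Analysis configuration with field-standard defaults
#'
#' Collects every stage parameter of the two workflows. Numeric defaults
#' follow the values conventionally used for this assay: 0.8 um linking
#' distance, 5-frame gap closing, >1 um track-displacement filter, the
#' >3 um / 60 s motile rule, 8/10 px concentric ROI diameters, and a 5 um
#' peripheral band.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval_incell Seconds per frame for live-cell tracking
#'   (0.1 = 10 Hz).
#' @param frame_interval_invitro Seconds per frame for in vitro movies.
#' @param max_link,max_gap LAP linking distance (um) and gap closing
#'   (frames).
#' @param min_track_displacement Track filter threshold, um.
#' @param motile_min_displacement,motile_window Motile-count rule (um, s).
#' @param inner_diameter_px,outer_diameter_px Concentric ROI diameters.
#' @param detection_diameter_px,detection_threshold LoG detector scale and
#'   quality threshold.
#' @param classify_window,classify_thresholds Motion-state segmentation
#'   window (frames) and threshold overrides (see [classify_segments()]).
#' @param speed_threshold,min_run_duration Kymograph run extraction: minimum
#'   smoothed speed (um/s) and duration (s).
#' @param band_um Peripheral band width, um.
#' @param imv_dims_nm,iev_dims_nm Virion tri-axial dimensions, nm.
#' @param out_dir Optional output directory for reports.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1,
                            pixel_size = 0.1,
                            frame_interval_incell = 0.1,
                            frame_interval_invitro = 1,
                            max_link = 0.8,
                            max_gap = 5,
                            min_track_displacement = 1,
                            motile_min_displacement = 3,
                            motile_window = 60,
                            inner_diameter_px = 8,
                            outer_diameter_px = 10,
                            detection_diameter_px = 4,
                            detection_threshold = 20,
                            classify_window = 15,
                            classify_thresholds = list(),
                            speed_threshold = 0.1,
                            min_run_duration = 3,
                            band_um = 5,
                            imv_dims_nm = c(350, 280, 200),
                            iev_dims_nm = c(440, 380, 260),
                            out_dir = NULL) {
  cfg <- list(seed = seed, pixel_size = pixel_size,
              frame_interval_incell = frame_interval_incell,
              frame_interval_invitro = frame_interval_invitro,
              max_link = max_link, max_gap = max_gap,
              min_track_displacement = min_track_displacement,
              motile_min_displacement = motile_min_displacement,
              motile_window = motile_window,
              inner_diameter_px = inner_diameter_px,
              outer_diameter_px = outer_diameter_px,
              detection_diameter_px = detection_diameter_px,
              detection_threshold = detection_threshold,
              classify_window = classify_window,
              classify_thresholds = classify_thresholds,
              speed_threshold = speed_threshold,
              min_run_duration = min_run_duration,
              band_um = band_um,
              imv_dims_nm = imv_dims_nm, iev_dims_nm = iev_dims_nm,
              out_dir = out_dir)
  stopifnot(cfg$max_link > 0, cfg$max_gap >= 0, cfg$pixel_size > 0,
            cfg$outer_diameter_px > cfg$inner_diameter_px)
  class(cfg) <- "analysis_config"
  cfg
}

#' Simulate and analyse an in vitro motility experiment
#'
#' Generates fields of surface-attached microtubules with one planted run
#' per microtubule, renders the movies, detects spots frame by frame,
#' projects the detections onto their microtubule paths, and extracts
#' constant-velocity runs. Runs are planted at `speed_um_s` (optionally with
#' normal spread `speed_sd`); this is the generator+pipeline pair used for
#' velocity-recovery validation.
#'
#' @param n_runs Total number of planted runs (split into fields of
#'   `runs_per_field`).
#' @param speed_um_s Mean planted speed, um/s.
#' @param speed_sd Between-run s.d. of planted speeds (0 = all identical).
#' @param duration_s Planted run duration, s.
#' @param config An [analysis_config()].
#' @param optics Optional [optics_model()] override.
#' @param localization_noise_sd Per-frame position jitter, um.
#' @param runs_per_field Planted runs (= microtubules) per rendered field.
#' @return List with `runs` (extracted), `truth` (planted), `summary`
#'   (from [summarize_runs()]), `motility_rate` (per min per mm),
#'   `total_mt_length_mm`, `imaging_minutes`, and the first field's
#'   `kymograph` for inspection.
#' @export
simulate_invitro_experiment <- function(n_runs = 20, speed_um_s = 0.66,
                                        speed_sd = 0, duration_s = 12,
                                        config = analysis_config(),
                                        optics = NULL,
                                        localization_noise_sd = 0.02,
                                        runs_per_field = 10) {
  if (is.null(optics)) {
    optics <- optics_model(pixel_size = config$pixel_size, psf_sigma = 1.0,
                           background_level = 50, camera_offset = 100,
                           read_noise_sd = 2)
  }
  set.seed(config$seed)
  n_fields <- ceiling(n_runs / runs_per_field)
  field_seeds <- sample.int(2^30, n_fields)
  speeds <- if (speed_sd > 0) {
    stats::rnorm(n_runs, speed_um_s, speed_sd)
  } else {
    rep(speed_um_s, n_runs)
  }
  n_frames <- ceiling(duration_s / config$frame_interval_invitro) + 2
  all_runs <- list(); all_truth <- list(); kymo <- NULL
  total_mt_um <- 0
  for (fi in seq_len(n_fields)) {
    idx <- ((fi - 1) * runs_per_field + 1):min(fi * runs_per_field, n_runs)
    k <- length(idx)
    mt <- data.frame(mt_id = seq_len(k),
                     x0_um = 0.9, y0_um = 1.4 + (seq_len(k) - 1) * 1.1,
                     x1_um = 11.9, y1_um = 1.4 + (seq_len(k) - 1) * 1.1,
                     polarity = "plus_at_end")
    plan <- data.frame(run_id = idx, mt_id = seq_len(k),
                       speed_um_s = pmax(0, speeds[idx]),
                       start_time_s = 0, duration_s = duration_s,
                       start_offset_um = 0.5, direction = "plus",
                       end_behaviour = "reach_end_stop")
    sim <- make_invitro_movie(mt, plan, optics,
                              frame_interval = config$frame_interval_invitro,
                              n_frames = n_frames, field_size = 128,
                              localization_noise_sd = localization_noise_sd,
                              seed = field_seeds[fi])
    total_mt_um <- total_mt_um + sum(sim$mt_layout$length_um)
    det <- detect_movie(sim$movie, config)
    traces <- project_detections_to_paths(det, mt, config$pixel_size,
                                          config$frame_interval_invitro)
    runs <- extract_runs(traces,
                         frame_interval = config$frame_interval_invitro,
                         min_duration = config$min_run_duration,
                         speed_threshold = config$speed_threshold,
                         mt_length_um = vapply(traces, function(tr)
                           sim$mt_layout$length_um[
                             sim$mt_layout$mt_id == tr$mt_id[1]], numeric(1)))
    if (nrow(runs)) {
      runs$mt_id <- runs$mt_id + (fi - 1) * 1000L # field-unique mt ids
      all_runs[[fi]] <- runs
    }
    tr <- sim$truth
    tr$mt_id <- tr$mt_id + (fi - 1) * 1000L
    all_truth[[fi]] <- tr
    if (fi == 1L) {
      kymo <- build_kymograph(sim$movie,
                              cbind(c(mt$x0_um[1], mt$x1_um[1]),
                                    c(mt$y0_um[1], mt$y1_um[1])),
                              line_width_px = 3,
                              pixel_size = config$pixel_size,
                              frame_interval = config$frame_interval_invitro)
    }
  }
  runs <- if (length(all_runs)) do.call(rbind, all_runs) else extract_runs(list())
  truth <- do.call(rbind, all_truth)
  pol <- data.frame(mt_id = unique(truth$mt_id), polarity = "plus_at_end")
  imaging_minutes <- n_frames * config$frame_interval_invitro / 60
  n_motile <- if (nrow(runs)) length(unique(paste(runs$mt_id, runs$trace)))
              else 0L
  list(runs = runs, truth = truth,
       summary = summarize_runs(runs, pol),
       motility_rate = motility_rate(n_motile, imaging_minutes,
                                     total_mt_um / 1000),
       n_motile = n_motile,
       total_mt_length_mm = total_mt_um / 1000,
       imaging_minutes = imaging_minutes,
       kymograph = kymo)
}

# LoG-detect every frame of a movie; returns a per-frame detection table
detect_movie <- function(movie, config) {
  do.call(rbind, lapply(seq_along(movie), function(f) {
    d <- detect_spots(movie[[f]], config$detection_diameter_px,
                      config$detection_threshold, subpixel = TRUE)
    if (!nrow(d)) return(NULL)
    data.frame(frame = f, x_um = d$x_px * config$pixel_size,
               y_um = d$y_px * config$pixel_size, quality = d$quality)
  }))
}

# assign detections to the nearest microtubule (within assign_radius) and
# project them to arclength, yielding one trace per microtubule
project_detections_to_paths <- function(detections, mt_layout, pixel_size,
                                        frame_interval, assign_radius = 0.5) {
  if (is.null(detections) || !nrow(detections)) return(list())
  traces <- list()
  for (k in seq_len(nrow(mt_layout))) {
    mt <- mt_layout[k, ]
    len <- sqrt((mt$x1_um - mt$x0_um)^2 + (mt$y1_um - mt$y0_um)^2)
    ux <- (mt$x1_um - mt$x0_um) / len; uy <- (mt$y1_um - mt$y0_um) / len
    dx <- detections$x_um - mt$x0_um; dy <- detections$y_um - mt$y0_um
    s <- dx * ux + dy * uy
    perp <- abs(-dx * uy + dy * ux)
    sel <- perp <= assign_radius & s >= -assign_radius & s <= len + assign_radius
    if (!any(sel)) next
    d <- detections[sel, , drop = FALSE]
    d$s_um <- pmax(0, pmin(s[sel], len))
    # one point per frame: keep the highest-quality detection
    d <- d[order(d$frame, -d$quality), , drop = FALSE]
    d <- d[!duplicated(d$frame), , drop = FALSE]
    traces[[length(traces) + 1L]] <- data.frame(
      t_s = (d$frame - 1) * frame_interval, s_um = d$s_um,
      mt_id = mt$mt_id, run_id = mt$mt_id)
  }
  traces
}

#' Simulate and analyse an in-cell tracking experiment
#'
#' Generates 10 Hz trajectories alternating planted active-transport and
#' normal-diffusion phases, pools the per-frame positions into a detection
#' table, re-links them with the LAP tracker, filters by net displacement,
#' segments each track into motion states and summarises the recovered
#' active-transport statistics against the planted truth.
#'
#' @param n_tracks Number of simulated virions.
#' @param active_speed Planted active-transport speed, um/s.
#' @param active_duration_s,diffusive_duration_s Phase durations, s.
#' @param d_um2_s Diffusion coefficient of the diffusive phases, um^2/s.
#' @param n_phases Total number of alternating phases (starting active).
#' @param localization_noise_sd Localization noise, um (30 nm default).
#' @param config An [analysis_config()].
#' @return List with `tracks` (linked `track_set`), `segments`, `stats`
#'   (from [active_transport_stats()]), `n_motile`, `truth`.
#' @export
simulate_incell_experiment <- function(n_tracks = 100, active_speed = 0.61,
                                       active_duration_s = 3,
                                       diffusive_duration_s = 3,
                                       d_um2_s = 0.01, n_phases = 4,
                                       localization_noise_sd = 0.03,
                                       config = analysis_config()) {
  dt <- config$frame_interval_incell
  segs <- lapply(seq_len(n_phases), function(k) {
    if (k %% 2 == 1) {
      list(state = "active", duration_s = active_duration_s,
           v_um_s = active_speed)
    } else {
      list(state = "normal_diffusion", duration_s = diffusive_duration_s,
           d_um2_s = d_um2_s)
    }
  })
  plan <- trajectory_plan(segs, dt = dt,
                          localization_noise_sd = localization_noise_sd)
  sim <- make_trajectory_set(plan, n_tracks = n_tracks,
                             field_um = max(100, 3 * sqrt(n_tracks) * 10),
                             seed = config$seed)
  detections <- do.call(rbind, lapply(sim$tracks, function(tr) {
    data.frame(frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um)
  }))
  tracks <- link_spots(detections, max_link = config$max_link,
                       max_gap = config$max_gap, frame_interval = dt)
  tracks <- filter_by_displacement(tracks, config$min_track_displacement)
  segments <- lapply(tracks$tracks, classify_segments,
                     window = config$classify_window,
                     thresholds = config$classify_thresholds)
  list(tracks = tracks, segments = segments,
       stats = active_transport_stats(segments),
       n_motile = count_motile(tracks, config$motile_min_displacement,
                               config$motile_window),
       truth = sim$truth)
}

#' Run the motor-counting workflow end to end on synthetic data
#'
#' Simulates nanocage calibration standards (24/60/120/180 fluorophores per
#' particle), virion cohorts carrying tagged motors at knock-in expression
#' (true corrected complex count divided by the expression fold), and
#' parental/knock-in antibody-staining cohorts whose intensity ratio encodes
#' the fold; then runs detection, concentric-ROI measurement, through-origin
#' calibration, molecule and complex conversion, expression correction and
#' surface-density arithmetic.
#'
#' @param config An [analysis_config()].
#' @param true_imv_complexes,true_iev_complexes Ground-truth corrected motor
#'   complex numbers planted in the simulation.
#' @param imv_fold,iev_fold Ground-truth expression-correction folds.
#' @param n_spots_per_species Calibration spots per nanocage species.
#' @param n_virions Virions per cohort.
#' @param optics Optional [optics_model()] override.
#' @return A report list: `calibration` (the fitted curve), cohort tables,
#'   `imv`/`iev` results (mean molecules, complexes, estimated fold,
#'   corrected complexes, surface area, area per motor), and `manifest`.
#' @export
run_motor_counting <- function(config = analysis_config(),
                               true_imv_complexes = 139,
                               true_iev_complexes = 320,
                               imv_fold = 2.14, iev_fold = 2.78,
                               n_spots_per_species = 50,
                               n_virions = 60, optics = NULL) {
  if (is.null(optics)) {
    optics <- optics_model(pixel_size = config$pixel_size, psf_sigma = 1.0,
                           photons_per_fluorophore = 100,
                           background_level = 50, camera_offset = 100,
                           read_noise_sd = 2)
  }
  set.seed(config$seed)
  seeds <- sample.int(2^30, 8)

  measure_scene <- function(species, seed, label) {
    sc <- make_spot_scene(species, optics, field_size = 256,
                          min_separation = 14, seed = seed)
    do.call(rbind, lapply(names(sc$images), function(ch) {
      img <- sc$images[[ch]]
      det <- detect_spots(img, config$detection_diameter_px,
                          config$detection_threshold)
      m <- measure_spots(img, det, config$inner_diameter_px,
                         config$outer_diameter_px)
      m <- m[m$valid & !m$crowded, , drop = FALSE]
      # label detections by the nearest truth spot
      tru <- sc$truth[sc$truth$channel == as.integer(ch), ]
      nearest <- vapply(seq_len(nrow(m)), function(k) {
        which.min((tru$x_px - m$x_px[k])^2 + (tru$y_px - m$y_px[k])^2)
      }, integer(1))
      m$copy_number <- tru$copy_number[nearest]
      m$cohort <- label
      m
    }))
  }

  standards <- measure_scene(
    data.frame(copy_number = c(24, 60, 120, 180),
               n_spots = n_spots_per_species), seeds[1], "nanocage")
  curve <- fit_calibration(data.frame(copy_number = standards$copy_number,
                                      intensity = standards$corrected_intensity))

  cohort_result <- function(true_complexes, fold, seed_v, seed_ref,
                            seed_tag, dims_nm) {
    # knock-in virions carry true/fold complexes = 2*true/fold fluorophores
    molecules_tagged <- 2 * true_complexes / fold
    vir <- measure_scene(data.frame(copy_number = molecules_tagged,
                                    n_spots = n_virions), seed_v, "virion")
    molecules <- intensity_to_molecules(vir$corrected_intensity, curve)
    complexes <- molecules_to_complexes(molecules)
    # antibody cohorts: parental vs knock-in staining, intensity ratio = fold
    ref <- measure_scene(data.frame(copy_number = 300, n_spots = n_virions),
                         seed_ref, "parental_ab")
    tag <- measure_scene(data.frame(copy_number = 300 / fold,
                                    n_spots = n_virions), seed_tag,
                         "knockin_ab")
    fold_est <- expression_correction_factor(ref$corrected_intensity,
                                             tag$corrected_intensity)
    mean_cx <- mean(complexes)
    corrected <- corrected_mean_complexes(mean_cx, fold_est)
    area <- ellipsoid_surface_area(dims_nm)
    list(virions = vir, mean_molecules = mean(molecules),
         sem_molecules = stats::sd(molecules) / sqrt(length(molecules)),
         mean_complexes = mean_cx, fold_estimate = fold_est,
         corrected_mean_complexes = corrected,
         surface_area_nm2 = area,
         area_per_motor_nm2 = area_per_motor(area, max(1, corrected)),
         true_complexes = true_complexes, true_fold = fold)
  }

  imv <- cohort_result(true_imv_complexes, imv_fold, seeds[2], seeds[3],
                       seeds[4], config$imv_dims_nm)
  iev <- cohort_result(true_iev_complexes, iev_fold, seeds[5], seeds[6],
                       seeds[7], config$iev_dims_nm)

  report <- list(calibration = curve, standards = standards,
                 imv = imv, iev = iev,
                 manifest = list(seed = config$seed,
                                 config = unclass(config),
                                 optics = unclass(optics),
                                 n_spots_per_species = n_spots_per_species,
                                 n_virions = n_virions))
  maybe_write_report(report, config, "motor_counting_report.json")
  report
}

#' Run the motility workflow end to end on synthetic data
#'
#' In-cell arm: trajectory simulation, LAP re-linking, displacement filter,
#' motion-state segmentation, active-run statistics and motile counts.
#' In vitro arm: movie simulation, detection, path projection, run
#' extraction, motility-rate normalisation and directionality summary.
#'
#' @param config An [analysis_config()].
#' @param incell,invitro Named lists of overrides forwarded to
#'   [simulate_incell_experiment()] and [simulate_invitro_experiment()].
#' @return A report list with `incell`, `invitro` and `manifest`.
#' @export
run_motility <- function(config = analysis_config(), incell = list(),
                         invitro = list()) {
  incell_res <- do.call(simulate_incell_experiment,
                        c(list(config = config), incell))
  invitro_res <- do.call(simulate_invitro_experiment,
                         c(list(config = config), invitro))
  report <- list(
    incell = list(stats = incell_res$stats, n_motile = incell_res$n_motile,
                  n_tracks = length(incell_res$tracks$tracks)),
    invitro = list(summary = invitro_res$summary[
                     setdiff(names(invitro_res$summary), "runs")],
                   n_motile = invitro_res$n_motile,
                   motility_rate = invitro_res$motility_rate,
                   total_mt_length_mm = invitro_res$total_mt_length_mm,
                   imaging_minutes = invitro_res$imaging_minutes),
    manifest = list(seed = config$seed, config = unclass(config)))
  maybe_write_report(report, config, "motility_report.json")
  list(report = report, incell = incell_res, invitro = invitro_res)
}

# write the numeric content of a report (plus its manifest) as JSON
maybe_write_report <- function(report, config, filename) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      out <- lapply(x, keep)
      out[!vapply(out, is.null, logical(1))]
    } else if (is.numeric(x) || is.character(x) || is.logical(x)) {
      x
    } else {
      NULL
    }
  }
  path <- file.path(config$out_dir, filename)
  jsonlite::write_json(keep(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
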
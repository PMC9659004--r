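test_that("noise-free spot scenes conserve integrated flux exactly", {
  op <- noise_free_optics(photons_per_fluorophore = 100)
  sc <- make_spot_scene(data.frame(copy_number = 60, n_spots = 1),
                        op, field_size = 32, min_separation = 5, seed = 1)
  expect_equal(sum(sc$images[[1]]), 60 * 100, tolerance = 1e-9)

  # several species: total flux is the sum over all planted spots
  op2 <- noise_free_optics(photons_per_fluorophore = 50, camera_offset = 10)
  spec <- data.frame(copy_number = c(24, 120), n_spots = c(2, 3))
  sc2 <- make_spot_scene(spec, op2, field_size = 96, min_separation = 10,
                         seed = 2)
  total <- sum(sc2$images[[1]]) - 96^2 * 10
  expect_equal(total, sum(sc2$truth$copy_number) * 50, tolerance = 1e-6)
})

test_that("spot scenes are bit-identical under a fixed seed", {
  spec <- data.frame(copy_number = c(24, 60), n_spots = c(5, 5))
  a <- make_spot_scene(spec, optics_model(), 128, 10, seed = 42)
  b <- make_spot_scene(spec, optics_model(), 128, 10, seed = 42)
  expect_identical(a, b)
  c <- make_spot_scene(spec, optics_model(), 128, 10, seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("every rendered spot appears exactly once in the truth table", {
  spec <- data.frame(copy_number = c(24, 60, 120, 180),
                     n_spots = c(7, 5, 3, 2))
  sc <- make_spot_scene(spec, optics_model(), 256, 12, seed = 3)
  expect_equal(nrow(sc$truth), sum(spec$n_spots))
  expect_false(any(duplicated(sc$truth$id)))
  expect_equal(as.vector(table(sc$truth$copy_number)[
    as.character(spec$copy_number)]), spec$n_spots)
})

test_that("impossible spot placement fails naming the constraint", {
  spec <- data.frame(copy_number = 60, n_spots = 50)
  expect_error(
    make_spot_scene(spec, optics_model(), field_size = 24,
                    min_separation = 10, seed = 1),
    "min_separation")
})

test_that("mean rendered flux is proportional to copy number", {
  op <- optics_model(photons_per_fluorophore = 100, psf_sigma = 1,
                     background_level = 20)
  spec <- data.frame(copy_number = c(24, 60, 120, 180), n_spots = 30)
  sc <- make_spot_scene(spec, op, field_size = 300, min_separation = 14,
                        seed = 4)
  img <- sc$images[[1]]
  m <- measure_spots(img, data.frame(x_px = sc$truth$x_px,
                                     y_px = sc$truth$y_px))
  means <- tapply(m$corrected_intensity[m$valid],
                  sc$truth$copy_number[m$valid], mean)
  ratio <- means / (as.numeric(names(means)) * 100)
  expect_true(all(abs(ratio - 1) < 0.03))
})

test_that("in vitro runs obey the planted kinematics", {
  mt <- data.frame(mt_id = 1, x0_um = 1, y0_um = 5, x1_um = 11, y1_um = 5,
                   polarity = "plus_at_end")
  plan <- data.frame(run_id = 1, mt_id = 1, speed_um_s = 0.5,
                     start_time_s = 0, duration_s = 10, start_offset_um = 1,
                     direction = "plus", end_behaviour = "reach_end_stop")
  sim <- make_invitro_movie(mt, plan, noise_free_optics(), frame_interval = 1,
                            n_frames = 11, seed = 1)
  expect_equal(sim$truth$net_displacement_um, 5.0, tolerance = 1e-12)
  # collinear with the (horizontal) microtubule
  expect_true(all(abs(sim$positions$y_um - 5) < 1e-12))
  expect_equal(diff(range(sim$positions$s_um)), 5.0, tolerance = 1e-12)
})

test_that("a virion that reaches the tip stays there; detachers vanish", {
  mt <- data.frame(mt_id = 1, x0_um = 1, y0_um = 5, x1_um = 6, y1_um = 5,
                   polarity = "plus_at_end")
  plan <- data.frame(run_id = 1:2, mt_id = 1, speed_um_s = 1,
                     start_time_s = 0, duration_s = 20, start_offset_um = 0,
                     direction = "plus",
                     end_behaviour = c("reach_end_stop", "detach"))
  sim <- make_invitro_movie(mt, plan, noise_free_optics(), frame_interval = 1,
                            n_frames = 10, seed = 1)
  p1 <- sim$positions[sim$positions$run_id == 1, ]
  expect_true(all(p1$s_um[p1$t_s >= 5] == 5)) # stalls at the 5 um tip
  p2 <- sim$positions[sim$positions$run_id == 2, ]
  expect_true(all(!p2$visible[p2$t_s > 5]))
})

test_that("a run that overruns its microtubule without an end fate errors", {
  mt <- data.frame(mt_id = 1, x0_um = 1, y0_um = 5, x1_um = 4, y1_um = 5,
                   polarity = "plus_at_end")
  plan <- data.frame(run_id = 1, mt_id = 1, speed_um_s = 1,
                     start_time_s = 0, duration_s = 20, start_offset_um = 0,
                     direction = "plus", end_behaviour = NA)
  expect_error(make_invitro_movie(mt, plan, noise_free_optics(),
                                  n_frames = 5, seed = 1),
               "end_behaviour")
})

test_that("planted run speeds drawn from a distribution match its mean", {
  set.seed(99)
  speeds <- rnorm(20, 0.66, 0.14)
  mt <- data.frame(mt_id = 1:20, x0_um = 1,
                   y0_um = seq(2, 40, by = 2), x1_um = 21,
                   y1_um = seq(2, 40, by = 2), polarity = "plus_at_end")
  plan <- data.frame(run_id = 1:20, mt_id = 1:20, speed_um_s = speeds,
                     start_time_s = 0, duration_s = 10, start_offset_um = 1,
                     direction = "plus", end_behaviour = "reach_end_stop")
  sim <- make_invitro_movie(mt, plan, noise_free_optics(), frame_interval = 1,
                            n_frames = 11, field_size = c(420, 230), seed = 5)
  emp <- sim$truth$net_displacement_um / 10
  se <- 0.14 / sqrt(20)
  expect_lt(abs(mean(emp) - 0.66), 3 * se)
})

test_that("trajectory generator obeys the stated motion-state laws", {
  # active kinematics: exact net displacement
  p <- trajectory_plan(list(list(state = "active", duration_s = 60,
                                 v_um_s = 0.61)), dt = 0.1)
  ts <- make_trajectory_set(p, n_tracks = 1, seed = 1)
  tr <- ts$tracks[[1]]
  n <- nrow(tr)
  net <- sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2)
  expect_equal(net, 36.6, tolerance = 1e-9)

  # normal diffusion MSD slope ~ 4D (average over tracks)
  pd <- trajectory_plan(list(list(state = "normal_diffusion",
                                  duration_s = 100, d_um2_s = 0.05)),
                        dt = 0.1)
  tsd <- make_trajectory_set(pd, n_tracks = 10, seed = 2)
  lags <- 1:10
  msd <- rowMeans(vapply(tsd$tracks, track_msd, numeric(length(lags)),
                         lags = lags))
  slope <- sum(msd * lags * 0.1) / sum((lags * 0.1)^2)
  expect_lt(abs(slope - 4 * 0.05) / (4 * 0.05), 0.15)

  # subdiffusion: fitted MSD exponent < 0.9
  psub <- trajectory_plan(list(list(state = "subdiffusion", duration_s = 100,
                                    d_um2_s = 0.05, hurst = 0.3)), dt = 0.1)
  tss <- make_trajectory_set(psub, n_tracks = 5, seed = 3)
  msds <- rowMeans(vapply(tss$tracks, track_msd, numeric(length(lags)),
                          lags = lags))
  alpha <- coef(lm(log(msds) ~ log(lags)))[[2]]
  expect_lt(alpha, 0.9)
  expect_gt(alpha, 0.3)

  # confinement: no point farther than L from the segment centre
  pc <- trajectory_plan(list(list(state = "confined", duration_s = 60,
                                  d_um2_s = 0.05, radius_um = 0.2)),
                        dt = 0.1)
  tsc <- make_trajectory_set(pc, n_tracks = 3, seed = 4)
  for (tr in tsc$tracks) {
    r <- sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2)
    expect_lte(max(r), 0.2 + 1e-12)
  }
})

test_that("trajectory truth labels every point exactly once", {
  p <- trajectory_plan(list(
    list(state = "active", duration_s = 3, v_um_s = 0.6),
    list(state = "normal_diffusion", duration_s = 3, d_um2_s = 0.01)),
    dt = 0.1)
  ts <- make_trajectory_set(p, n_tracks = 4, seed = 5)
  for (i in seq_along(ts$tracks)) {
    lab <- ts$truth[ts$truth$track_id == i, ]
    expect_equal(nrow(lab), nrow(ts$tracks[[i]]))
    expect_setequal(unique(lab$state), c("active", "normal_diffusion"))
  }
})

test_that("trajectory plans validate their parameters", {
  expect_error(trajectory_plan(list(list(state = "warp", duration_s = 1))),
               "unknown motion state")
  expect_error(trajectory_plan(list(list(state = "confined", duration_s = 1,
                                         d_um2_s = 0.1, radius_um = -1))),
               "radius_um")
  expect_error(trajectory_plan(list(list(state = "subdiffusion",
                                         duration_s = 1, d_um2_s = 0.1,
                                         hurst = 0.7))),
               "hurst")
  expect_error(trajectory_plan(list(list(state = "active", duration_s = -3,
                                         v_um_s = 1))),
               "duration")
})

test_that("uniform spots in a square cell put ~75% in a 5 um band", {
  sc <- make_cell_scene(square_cell(20), list(n = 4000), pixel_size = 0.1,
                        band_um = 5, seed = 6)
  frac <- mean(sc$spots$region == "peripheral")
  # area ratio (20^2 - 10^2) / 20^2 = 0.75; binomial se ~ 0.0068
  expect_lt(abs(frac - 0.75), 4 * sqrt(0.75 * 0.25 / 4000))
})

test_that("cell scenes handle degenerate placements", {
  sc0 <- make_cell_scene(square_cell(20), list(n = 0), seed = 1)
  expect_equal(nrow(sc0$spots), 0)
  sci <- make_cell_scene(square_cell(20),
                         list(n_interior = 50, n_peripheral = 0), seed = 2)
  expect_true(all(sci$spots$region == "interior"))
  expect_error(
    make_cell_scene(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)),
                    list(n = 10)),
    "self-intersecting")
})
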
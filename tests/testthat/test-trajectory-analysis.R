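test_that("the assignment solver matches brute-force permutation search", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    asg <- virocount:::solve_assignment(C)
    expect_equal(sort(asg), seq_len(n)) # a permutation
    expect_equal(sum(C[cbind(seq_len(n), asg)]),
                 brute_force_assignment_cost(C), tolerance = 1e-9)
  }
})

test_that("a static spot yields one track with all its points", {
  det <- data.frame(frame = 1:50, x_um = 2, y_um = 3)
  ts <- link_spots(det)
  expect_equal(length(ts$tracks), 1)
  expect_equal(nrow(ts$tracks[[1]]), 50)
  expect_false(any(ts$tracks[[1]]$interpolated))
})

test_that("two parallel spots never swap identity", {
  det <- do.call(rbind, lapply(1:40, function(f) {
    data.frame(frame = f, x_um = 0.05 * f + c(0, 0), y_um = c(0, 2),
               id = c("a", "b"))
  }))
  ts <- link_spots(det, max_link = 0.8)
  expect_equal(length(ts$tracks), 2)
  for (tr in ts$tracks) {
    ids <- det$id[tr$detection_id]
    expect_equal(length(unique(ids)), 1)
  }
})

test_that("gap closing bridges <= max_gap missing frames and no more", {
  mk <- function(missing) {
    frames <- setdiff(1:30, 11:(10 + missing))
    data.frame(frame = frames, x_um = 0.05 * frames, y_um = 0)
  }
  ts5 <- link_spots(mk(5), max_link = 0.8, max_gap = 5)
  expect_equal(length(ts5$tracks), 1)
  expect_equal(sum(ts5$tracks[[1]]$interpolated), 5)
  # interpolated positions are linear between the flanking detections
  tr <- ts5$tracks[[1]]
  expect_equal(tr$x_um, 0.05 * (1:30), tolerance = 1e-12)
  ts6 <- link_spots(mk(6), max_link = 0.8, max_gap = 5)
  expect_equal(length(ts6$tracks), 2)
})

test_that("linking conserves detections: each in exactly one track", {
  set.seed(32)
  p <- trajectory_plan(list(list(state = "normal_diffusion", duration_s = 5,
                                 d_um2_s = 0.02)), dt = 0.1)
  sim <- make_trajectory_set(p, n_tracks = 8, field_um = 60, seed = 33)
  det <- do.call(rbind, lapply(sim$tracks, function(tr) {
    data.frame(frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um)
  }))
  ts <- link_spots(det)
  assigned <- unlist(lapply(ts$tracks,
                            function(tr) tr$detection_id[!tr$interpolated]))
  expect_equal(sort(assigned), seq_len(nrow(det)))
})

test_that("missing frame metadata is rejected", {
  expect_error(link_spots(data.frame(x_um = 1, y_um = 2)), "frame")
})

test_that("the displacement filter keeps only net movers", {
  static <- data.frame(frame = 1:20, t_s = (0:19) * 0.1, x_um = 1, y_um = 1)
  mover <- data.frame(frame = 1:20, t_s = (0:19) * 0.1,
                      x_um = seq(0, 2, length.out = 20), y_um = 0)
  kept <- filter_by_displacement(list(static, mover), 1)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$x_um, mover$x_um)
  expect_equal(length(filter_by_displacement(list(static, mover), 0)), 2)
})

test_that("a noise-free ballistic track is one active segment with exact velocity", {
  tr <- data.frame(frame = 1:60, t_s = (0:59) * 0.1,
                   x_um = 0.61 * (0:59) * 0.1, y_um = 0)
  seg <- classify_segments(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "active")
  expect_equal(seg$velocity_um_s, 0.61, tolerance = 1e-12)
  expect_equal(seg$run_length_um, 0.61 * 5.9, tolerance = 1e-12)
})

test_that("confined tracks are labelled confined at >= 90% of points", {
  p <- trajectory_plan(list(list(state = "confined", duration_s = 30,
                                 d_um2_s = 0.05, radius_um = 0.2)),
                       dt = 0.1, localization_noise_sd = 0.01)
  sim <- make_trajectory_set(p, n_tracks = 3, seed = 34)
  for (tr in sim$tracks) {
    seg <- classify_segments(tr)
    states <- attr(seg, "point_states")
    expect_gte(mean(states == "confined"), 0.9)
  }
})

test_that("segments of one track tile it exactly without overlap", {
  p <- trajectory_plan(list(
    list(state = "active", duration_s = 5, v_um_s = 0.6),
    list(state = "normal_diffusion", duration_s = 5, d_um2_s = 0.01),
    list(state = "active", duration_s = 5, v_um_s = 0.6)),
    dt = 0.1, localization_noise_sd = 0.03)
  sim <- make_trajectory_set(p, n_tracks = 5, seed = 35)
  for (tr in sim$tracks) {
    seg <- classify_segments(tr)
    expect_equal(seg$start_frame[1], tr$frame[1])
    expect_equal(seg$end_frame[nrow(seg)], tr$frame[nrow(tr)])
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_frame[-1] == seg$end_frame[-nrow(seg)] + 1))
    }
    expect_equal(sum(seg$n_frames), nrow(tr))
  }
})

test_that("an active-diffusive-active plan yields two recovered active runs", {
  p <- trajectory_plan(list(
    list(state = "active", duration_s = 5, v_um_s = 0.6),
    list(state = "normal_diffusion", duration_s = 5, d_um2_s = 0.01),
    list(state = "active", duration_s = 5, v_um_s = 0.6)),
    dt = 0.1, localization_noise_sd = 0.03)
  sim <- make_trajectory_set(p, n_tracks = 10, seed = 36)
  agree <- numeric(0); n_active_runs <- integer(0)
  for (i in seq_along(sim$tracks)) {
    tr <- sim$tracks[[i]]
    seg <- classify_segments(tr)
    states <- attr(seg, "point_states")
    truth <- sim$truth$state[sim$truth$track_id == i]
    agree <- c(agree, mean(states == truth))
    n_active_runs <- c(n_active_runs, sum(seg$state == "active"))
  }
  expect_gte(mean(agree), 0.85)
  expect_gte(mean(n_active_runs == 2), 0.7)
})

test_that("motion-state accuracy >= 90% on well-separated regimes over seeds", {
  states <- c(active = "active", diff = "normal_diffusion",
              conf = "confined")
  acc <- numeric(0)
  for (seed in 1:20) {
    plans <- list(
      trajectory_plan(list(list(state = "active", duration_s = 20,
                                v_um_s = 0.5)), dt = 0.1,
                      localization_noise_sd = 0.02),
      trajectory_plan(list(list(state = "normal_diffusion", duration_s = 20,
                                d_um2_s = 0.02)), dt = 0.1,
                      localization_noise_sd = 0.02),
      trajectory_plan(list(list(state = "confined", duration_s = 20,
                                d_um2_s = 0.02, radius_um = 0.25)),
                      dt = 0.1, localization_noise_sd = 0.02))
    sim <- make_trajectory_set(plans, n_tracks = 3, seed = seed)
    for (i in seq_along(sim$tracks)) {
      seg <- classify_segments(sim$tracks[[i]])
      states_hat <- attr(seg, "point_states")
      truth <- sim$truth$state[sim$truth$track_id == i]
      acc <- c(acc, mean(states_hat == truth))
    }
  }
  expect_gte(mean(acc), 0.9)
})

test_that("active-transport statistics summarise segment arithmetic", {
  seg <- data.frame(start_frame = 1, end_frame = 601, n_frames = 601,
                    state = "active", velocity_um_s = 36.6 / 60,
                    run_length_um = 36.6)
  st <- active_transport_stats(seg)
  expect_equal(st$mean_velocity, 0.61)
  expect_equal(st$mean_run_length, 36.6)
  empty <- active_transport_stats(seg[0, ])
  expect_equal(empty$n_runs, 0L)
  expect_equal(empty$status, "no active runs")
})

test_that("motile counting applies the >3 um in 60 s rule", {
  static <- lapply(1:6, function(i) {
    data.frame(frame = 1:600, t_s = (0:599) * 0.1, x_um = i, y_um = 0)
  })
  expect_equal(count_motile(static), 0)
  movers <- lapply(1:4, function(i) {
    data.frame(frame = 1:600, t_s = (0:599) * 0.1,
               x_um = seq(0, 5, length.out = 600), y_um = 0)
  })
  expect_equal(count_motile(c(static, movers)), 4)
  # displacement outside the window does not count
  slow <- list(data.frame(frame = 1:1200, t_s = (0:1199) * 0.1,
                          x_um = seq(0, 4, length.out = 1200), y_um = 0))
  expect_equal(count_motile(slow, 3, 60), 0) # only 2 um within 60 s
})
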
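test_that("pure-noise kymographs yield no events", {
  for (s in c(1, 14, 28)) {
    set.seed(s)
    k <- kymograph(matrix(rnorm(500 * 100, 20, 5), 500, 100), 0.1, 0.1)
    expect_equal(nrow(detect_events(k)), 0L)
  }
})

test_that("a constant kymograph yields no events", {
  k <- kymograph(matrix(3, 100, 50), 0.1, 0.1)
  expect_equal(nrow(detect_events(k)), 0L)
})

test_that("three well-separated tracks are recovered with directions and velocities", {
  # oracle: the simulator's ground-truth track list
  cfg <- separated_tracks_config(3, seed = 11)
  sim <- simulate_transport_stream(cfg)
  k <- build_kymograph(sim$stream, neurite_path(cfg$path))
  ev <- detect_events(k, restrict_to = bleach_mask(k, cfg$bleach_window))
  expect_equal(nrow(ev), 3L)
  truth <- sim$tracks[order(sim$tracks$entry_time_s), ]
  expect_equal(ev$direction, truth$direction)
  expect_true(all(abs(ev$velocity_um_s / truth$mean_velocity_um_s - 1) < 0.1))
})

test_that("noiseless velocity fits are accurate to better than 2%", {
  for (s in c(4, 9)) {
    cfg <- separated_tracks_config(2, seed = s, noise = FALSE)
    sim <- simulate_transport_stream(cfg)
    k <- build_kymograph(sim$stream, neurite_path(cfg$path))
    ev <- detect_events(k, restrict_to = bleach_mask(k, cfg$bleach_window))
    expect_equal(nrow(ev), 2L)
    truth <- sim$tracks[order(sim$tracks$entry_time_s), ]
    expect_true(all(abs(ev$velocity_um_s / truth$mean_velocity_um_s - 1) <
                      0.02))
  }
})

test_that("a run shorter than min_displacement is not an event", {
  # oracle: ground-truth displacement of a vesicle entering 1.5 s before
  # the stream ends at 1 um/s is ~1.5 um, below the 2 um minimum
  cfg <- transport_sim_config(
    seed = 8, duration_s = 50, field_shape = c(12L, 120L),
    path = rbind(c(6, 10), c(6, 110)), n_vesicles = 1,
    velocity_range_um_s = c(1, 1), pause_prob_per_frame = 0,
    vesicle_amplitude = 50, background_level = 20, bleach_window = c(0, 10),
    bleach_factor = 0.3, read_noise_sd = 10, shot_noise = FALSE,
    entry_times_s = 48.5, directions = "anterograde")
  sim <- simulate_transport_stream(cfg)
  expect_lt(abs(sim$tracks$net_displacement_um), 2)
  k <- build_kymograph(sim$stream, neurite_path(cfg$path))
  ev <- detect_events(k, restrict_to = bleach_mask(k, cfg$bleach_window))
  expect_equal(nrow(ev), 0L)
})

test_that("raising the detection threshold never adds events", {
  # above the noise floor (>= 3 sd) candidate sets only shrink as the
  # threshold rises, so linked event counts cannot grow; below it, dense
  # noise candidates disrupt linking and the relation is not monotone
  cfg <- separated_tracks_config(4, seed = 2)
  sim <- simulate_transport_stream(cfg)
  k <- build_kymograph(sim$stream, neurite_path(cfg$path))
  n <- vapply(c(3, 4, 5, 6, 10), function(th)
    nrow(detect_events(k, event_params(detection_threshold_sd = th))),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("reversing kymograph rows swaps anterograde and retrograde", {
  cfg <- separated_tracks_config(4, seed = 7)
  sim <- simulate_transport_stream(cfg)
  k <- build_kymograph(sim$stream, neurite_path(cfg$path))
  kr <- kymograph(k$matrix[rev(seq_len(nrow(k$matrix))), ],
                  k$frame_interval_s, k$position_step_um)
  s1 <- summarize_events(detect_events(k), 50)
  s2 <- summarize_events(detect_events(kr), 50)
  expect_equal(s1$n_events, s2$n_events)
  expect_equal(s1$n_anterograde, s2$n_retrograde)
  expect_equal(s1$n_retrograde, s2$n_anterograde)
})

test_that("summaries count and convert to per-minute flux", {
  s0 <- summarize_events(detect_events(kymograph(matrix(1, 100, 30),
                                                 0.1, 0.1)), 50)
  expect_equal(s0$n_events, 0L)
  expect_equal(s0$flux_per_min, 0)
  ev <- structure(data.frame(
    event_id = 1:5, t_start_s = 1:5, t_end_s = 2:6,
    pos_start_um = 0, pos_end_um = c(3, 3, -3, -3, -3),
    direction = c("anterograde", "anterograde", rep("retrograde", 3)),
    velocity_um_s = c(1, 1, -1, -1, -1), n_points = 10L),
    class = c("transport_events", "data.frame"))
  s5 <- summarize_events(ev, 50)
  expect_equal(s5$n_events, 5L)
  expect_equal(s5$n_anterograde, 2L)
  expect_equal(s5$n_retrograde, 3L)
  expect_equal(s5$flux_per_min, 5 * 60 / 50)  # 6 per minute, by hand
})

test_that("a short kymograph warns and returns nothing", {
  k <- kymograph(matrix(rnorm(4 * 30), 4, 30), 0.1, 0.1)
  expect_warning(ev <- detect_events(k), "min_duration|rows")
  expect_equal(nrow(ev), 0L)
})
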
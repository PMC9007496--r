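test_that("stream has round(duration / frame_interval) frames", {
  cfg <- transport_sim_config(seed = 1, duration_s = 50,
                              frame_interval_s = 0.1, n_vesicles = 0,
                              shot_noise = FALSE, read_noise_sd = 0)
  expect_equal(n_frames(simulate_transport_stream(cfg)$stream), 500L)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- transport_sim_config(seed = 99, duration_s = 5, n_vesicles = 4)
  a <- simulate_transport_stream(cfg)
  b <- simulate_transport_stream(cfg)
  expect_identical(a$stream$frames, b$stream$frames)
  expect_identical(a$positions_um, b$positions_um)
})

test_that("empty noiseless scene is exactly the bleached background field", {
  cfg <- transport_sim_config(seed = 2, duration_s = 2, n_vesicles = 0,
                              shot_noise = FALSE, read_noise_sd = 0,
                              background_level = 20, bleach_factor = 0.3,
                              bleach_window = c(2, 8),
                              bleach_halfwidth_px = 3)
  st <- simulate_transport_stream(cfg)$stream
  f1 <- st$frames[, , 1]
  for (i in seq_len(n_frames(st)))
    expect_identical(st$frames[, , i], f1)
  # on-path pixels: path runs along row 8 from col 10 (arc 0) to col 120;
  # arc of (8, c) is (c - 10) * 0.1 um, so window [2, 8) covers ~cols 30..89
  # (stay a column clear of the boundary to avoid ties in float arc lengths)
  expect_true(all(f1[8, 31:88] == 20 * 0.3))
  expect_true(all(f1[8, c(10:28, 91:120)] == 20))
  expect_true(all(f1[1, ] == 20))  # far from the corridor
})

test_that("bleach contract: corridor attenuated by exactly bleach_factor", {
  cfg <- transport_sim_config(seed = 3, duration_s = 1, n_vesicles = 0,
                              shot_noise = FALSE, read_noise_sd = 0,
                              bleach_factor = 0.42, bleach_window = c(1, 9))
  f1 <- simulate_transport_stream(cfg)$stream$frames[, , 1]
  inside <- mean(f1[8, 25:95])
  outside <- mean(f1[8, c(12:18, 102:118)])
  expect_lt(abs(inside / outside - 0.42), 0.42 * 0.01)
})

test_that("constant-velocity vesicle lands where the kinematics say", {
  sim <- simulate_transport_stream(single_vesicle_config(1.0, 10))
  # 10 s at +1 um/s: ground-truth displacement ~10 um (99 frames advance)
  expect_equal(sim$tracks$mean_velocity_um_s, 1.0, tolerance = 1e-12)
  expect_gt(sim$tracks$net_displacement_um, 9.8)
  # oracle: argmax of the noiseless last frame sits ~100 px past entry col 10
  cols <- argmax_cols(sim$stream, path_row = 8)
  expect_lte(abs(cols[n_frames(sim$stream)] - (10 + 100)), 1)
})

test_that("track positions are monotone for a non-reversing vesicle", {
  for (s in 1:5) {
    cfg <- transport_sim_config(seed = s, duration_s = 20, n_vesicles = 3,
                                pause_prob_per_frame = 0.2,
                                shot_noise = FALSE, read_noise_sd = 0)
    sim <- simulate_transport_stream(cfg)
    for (v in seq_len(3)) {
      p <- sim$positions_um[, v]
      p <- p[!is.na(p)]
      if (length(p) < 2) next
      d <- diff(p)
      if (sim$tracks$direction[v] == "anterograde")
        expect_true(all(d >= 0)) else expect_true(all(d <= 0))
    }
  }
})

test_that("rendered spot mass is conserved while the spot is in-field", {
  cfg <- single_vesicle_config(1.0, 6)
  sim <- simulate_transport_stream(cfg)
  bg <- simulate_transport_stream(
    transport_sim_config(seed = 1, duration_s = 6, frame_interval_s = 0.1,
                         field_shape = c(16L, 130L),
                         path = rbind(c(8, 10), c(8, 120)), n_vesicles = 0,
                         bleach_window = c(0, 11), bleach_factor = 1,
                         shot_noise = FALSE, read_noise_sd = 0)
  )$stream$frames[, , 1]
  sigma_px <- 0.15 / 0.1
  expected_mass <- 50 * 2 * pi * sigma_px^2
  # frames 11..50: spot center is 7-16 px along, >= 4 sigma + 1 from edges
  masses <- vapply(11:50, function(i) sum(sim$stream$frames[, , i] - bg),
                   numeric(1))
  expect_true(all(abs(masses / expected_mass - 1) < 0.005))
  expect_lt(diff(range(masses)) / mean(masses), 0.005)
})

test_that("more vesicles launch more tracks through the bleach window", {
  crossing <- function(n_ves) {
    mean(vapply(1:8, function(s) {
      cfg <- transport_sim_config(seed = s, duration_s = 20,
                                  n_vesicles = n_ves, shot_noise = FALSE,
                                  read_noise_sd = 0)
      pos <- simulate_transport_stream(cfg)$positions_um
      sum(vapply(seq_len(ncol(pos)), function(v)
        any(!is.na(pos[, v]) & pos[, v] >= 0 & pos[, v] < 11), logical(1)))
    }, numeric(1)))
  }
  counts <- vapply(c(2, 6, 12), crossing, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("configuration errors are caught", {
  expect_error(transport_sim_config(seed = 1, path = rbind(c(1, 1))),
               "vertices")
  expect_error(transport_sim_config(seed = 1, bleach_factor = 0), "bleach")
  expect_error(transport_sim_config(seed = 1, bleach_window = c(0, 99)),
               "outside the path")
  expect_error(transport_sim_config(seed = 1,
                                    velocity_range_um_s = c(3, 1)),
               "velocity")
  expect_error(transport_sim_config(duration_s = 10), "seed")
})
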
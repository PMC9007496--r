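flat_trace <- function(f, dt = 0.25) {
  calcium_trace(seq(0, by = dt, length.out = length(f)), f, dt)
}

test_that("a constant trace has zero dF/F, activity, and peaks", {
  m <- compute_metrics(flat_trace(rep(100, 240)))
  expect_equal(m$f_min_baseline, 100)
  expect_true(all(m$dff == 0))
  expect_equal(m$total_activity, 0)
  expect_equal(m$n_peaks, 0L)
  expect_true(is.na(m$mean_peak_amplitude_dff))
})

test_that("a rectangular excursion gives its closed-form total activity", {
  # 10 samples of +50 over baseline 100: total activity 10 * 50 / 100 = 5
  f <- c(rep(100, 100), rep(150, 10), rep(100, 130))
  m <- compute_metrics(flat_trace(f))
  expect_identical(m$total_activity, 5)
  expect_equal(m$n_peaks, 1L)
  expect_equal(m$dff[m$peak_indices], 0.5)
})

test_that("metrics are invariant to intensity rescaling", {
  sim <- simulate_calcium_trace(calcium_sim_config(seed = 31))
  m1 <- compute_metrics(sim$trace)
  tr2 <- calcium_trace(sim$trace$time_s, sim$trace$fluorescence * 3.7, 0.25)
  m2 <- compute_metrics(tr2)
  expect_equal(m2$f_min_baseline, m1$f_min_baseline * 3.7, tolerance = 1e-12)
  expect_equal(m2$dff, m1$dff, tolerance = 1e-9)
  expect_equal(m2$total_activity, m1$total_activity, tolerance = 1e-9)
  expect_identical(m2$peak_indices, m1$peak_indices)
})

test_that("total activity of disjoint transients is additive", {
  mk <- function(onsets) {
    cfg <- calcium_sim_config(seed = 1, n_transients = length(onsets),
                              transient_amplitude_range = c(0.8, 0.8),
                              baseline_drift_amplitude = 0, noise_sd = 0,
                              onset_times_s = onsets)
    compute_metrics(simulate_calcium_trace(cfg)$trace)$total_activity
  }
  both <- mk(c(10, 45))
  expect_equal(both, mk(10) + mk(45), tolerance = 1e-9)
})

test_that("total activity grows with transient amplitude", {
  ta <- vapply(c(0.4, 0.8, 1.2, 1.6), function(a) {
    cfg <- calcium_sim_config(seed = 12, n_transients = 3,
                              transient_amplitude_range = c(a, a))
    compute_metrics(simulate_calcium_trace(cfg)$trace)$total_activity
  }, numeric(1))
  expect_true(all(diff(ta) > 0))
})

test_that("peaks and amplitudes are recovered from simulated traces", {
  # oracle: the simulator's ground-truth transient list, low-noise regime
  for (s in 1:10) {
    sim <- simulate_calcium_trace(calcium_sim_config(seed = s,
                                                     noise_sd = 1.0))
    m <- compute_metrics(sim$trace)
    expect_equal(m$n_peaks, length(sim$truth$onset_times_s))
    for (j in seq_along(sim$truth$onset_times_s)) {
      i <- which.min(abs(m$peak_times_s - sim$truth$onset_times_s[j]))
      expect_lt(abs(m$dff[m$peak_indices[i]] /
                      sim$truth$peak_amplitudes_dff[j] - 1), 0.1)
    }
  }
})

test_that("normalization to control divides by the control mean", {
  self <- normalize_to_control(c(2, 4, 6), c(2, 4, 6))
  expect_equal(mean(self$control), 1)
  expect_equal(normalize_to_control(3, c(2, 4))$values, 1)  # 3 / mean(2,4)
  expect_equal(normalize_to_control(c(0, 0), c(5, 5))$values, c(0, 0))
  expect_error(normalize_to_control(1, c(-1, 1)), "zero")
  expect_error(normalize_to_control(1, numeric(0)), "non-empty")
})

test_that("degenerate traces are rejected", {
  expect_error(compute_metrics(flat_trace(rep(1, 2))), "window")
  tr <- flat_trace(rep(100, 240))
  expect_error(compute_metrics(tr, calcium_params(-1)), "> 0")
})

test_that("ROI extraction averages the right pixels", {
  fr <- array(1, dim = c(10, 10, 3))
  fr[2:4, 2:4, ] <- 9
  st <- image_stream(fr, 0.25, 0.1)
  tr <- extract_roi_trace(st, list(rows = c(2, 4), cols = c(2, 4)))
  expect_equal(tr$fluorescence, rep(9, 3))
  expect_equal(tr$frame_interval_s, 0.25)
  # polygon covering the same block (square around pixel centers 2..4)
  poly <- rbind(c(1.5, 1.5), c(1.5, 4.5), c(4.5, 4.5), c(4.5, 1.5))
  tp <- extract_roi_trace(st, list(polygon = poly))
  expect_equal(tp$fluorescence, rep(9, 3))
  expect_error(extract_roi_trace(st, list()), "roi")
})
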
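# Shared fixtures and independent oracles used across test files.

# Noiseless single-vesicle scene: anterograde at a fixed speed, entering at
# t = 0 at the cell-body end of a straight horizontal path.
single_vesicle_config <- function(speed_um_s = 1.0, duration_s = 10,
                                  seed = 1, noise = FALSE) {
  transport_sim_config(
    seed = seed, duration_s = duration_s, frame_interval_s = 0.1,
    pixel_size_um = 0.1, field_shape = c(16L, 130L),
    path = rbind(c(8, 10), c(8, 120)),
    n_vesicles = 1, velocity_range_um_s = c(speed_um_s, speed_um_s),
    pause_prob_per_frame = 0, vesicle_amplitude = 50,
    vesicle_sigma_um = 0.15, background_level = 20,
    bleach_window = c(0, 11), bleach_factor = 1,
    read_noise_sd = if (noise) 10 else 0, shot_noise = noise,
    entry_times_s = 0, directions = "anterograde")
}

# Oracle: per-frame argmax of a noiseless stream along a horizontal path at
# row `path_row`, returned as column indices of the field.
argmax_cols <- function(stream, path_row) {
  vapply(seq_len(n_frames(stream)),
         function(i) which.max(stream$frames[path_row, , i]),
         integer(1))
}

# Oracle: continuous-time maximum of the difference-of-exponentials
# transient kernel, by dense-grid evaluation (independent of the closed
# form used in the simulator).
kernel_max_dense <- function(rise_tau, decay_tau, dt = 1e-5, t_max = 20) {
  t <- seq(0, t_max, by = dt)
  y <- exp(-t / decay_tau) - exp(-t / rise_tau)
  list(value = max(y), t_peak = t[which.max(y)])
}

# Hand computation of the modified Thompson-Tau cutoff tau * s for a sample,
# using the printed critical value t_{alpha/2, n-2} (default: n = 5,
# t_{0.025,3} = 3.182).
tau_cutoff_hand <- function(x, t_crit = 3.182) {
  n <- length(x)
  tau <- t_crit * (n - 1) / (sqrt(n) * sqrt(n - 2 + t_crit^2))
  tau * sd(x)
}
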
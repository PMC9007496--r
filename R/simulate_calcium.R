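#' Configuration for the calcium-trace simulator
#'
#' Emulates a somatic GCaMP6f recording: a slowly drifting baseline carrying
#' sparse calcium transients with fast rise and slower decay, sampled at the
#' acquisition regime the package targets (60 s at 250 ms/frame, 240
#' samples).  Transients are difference-of-exponential kernels
#' \eqn{g(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}}, each rescaled so its
#' continuous-time maximum equals the drawn dF/F amplitude, applied
#' multiplicatively to the baseline: \eqn{F(t) = B(t)(1 + \sum_j A_j g_j(t))}.
#'
#' @param duration_s recording duration, seconds.
#' @param frame_interval_s sampling interval, seconds.
#' @param baseline_level mean baseline fluorescence, intensity units.
#' @param baseline_drift_amplitude amplitude of a slow sinusoidal baseline
#'   drift (one period over the recording), intensity units.
#' @param n_transients number of transients.
#' @param transient_amplitude_range `(min, max)` peak dF/F per transient.
#' @param rise_tau_s rise time constant, seconds.
#' @param decay_tau_s decay time constant, seconds; must exceed `rise_tau_s`.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param min_onset_gap_s minimum spacing between transient onsets, seconds.
#' @param onset_times_s optional fixed onset times (overrides random draws).
#' @param seed integer seed; mandatory.
#' @return A `calcium_sim_config` list.
#' @export
calcium_sim_config <- function(seed,
                               duration_s = 60,
                               frame_interval_s = 0.25,
                               baseline_level = 100,
                               baseline_drift_amplitude = 0.5,
                               n_transients = 3,
                               transient_amplitude_range = c(0.5, 1.5),
                               rise_tau_s = 0.25,
                               decay_tau_s = 1.0,
                               noise_sd = 1.5,
                               min_onset_gap_s = 5,
                               onset_times_s = NULL) {
  if (missing(seed)) stop_config("seed is mandatory")
  check_scalar(duration_s, "duration_s")
  check_scalar(frame_interval_s, "frame_interval_s")
  if (baseline_level <= 0) stop_config("baseline_level must be > 0")
  if (n_transients < 0) stop_config("n_transients must be >= 0")
  if (!(decay_tau_s > rise_tau_s && rise_tau_s > 0))
    stop_config("need decay_tau_s > rise_tau_s > 0")
  if (!is.null(onset_times_s)) {
    if (length(onset_times_s) != n_transients)
      stop_config("onset_times_s must have length n_transients")
    if (is.unsorted(onset_times_s, strictly = TRUE) ||
        any(onset_times_s < 0 | onset_times_s > duration_s))
      stop_config("onsets must be strictly increasing within [0, duration_s]")
  }
  structure(list(duration_s = duration_s, frame_interval_s = frame_interval_s,
                 baseline_level = baseline_level,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 n_transients = as.integer(n_transients),
                 transient_amplitude_range = transient_amplitude_range,
                 rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 noise_sd = noise_sd, min_onset_gap_s = min_onset_gap_s,
                 onset_times_s = onset_times_s, seed = as.integer(seed)),
            class = "calcium_sim_config")
}

# Difference-of-exponentials transient kernel, unit peak, zero before onset.
transient_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  norm <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out <- numeric(length(t))
  p <- t >= 0
  out[p] <- (exp(-t[p] / decay_tau) - exp(-t[p] / rise_tau)) / norm
  out
}

#' Simulate a somatic calcium trace
#'
#' @param config a [calcium_sim_config()].
#' @return A list with components
#'   \describe{
#'     \item{trace}{a [calcium_trace()] of
#'       `round(duration_s / frame_interval_s)` samples.}
#'     \item{truth}{list with `onset_times_s`, `peak_amplitudes_dff` and
#'       `true_baseline` (the drifting baseline at every sample).}
#'   }
#' @examples
#' sim <- simulate_calcium_trace(calcium_sim_config(seed = 7))
#' length(sim$trace$fluorescence)  # 240 samples at the default regime
#' @export
simulate_calcium_trace <- function(config) {
  if (!inherits(config, "calcium_sim_config"))
    stop_config("config must be a calcium_sim_config")
  cfg <- config
  n <- as.integer(round(cfg$duration_s / cfg$frame_interval_s))
  t <- (seq_len(n) - 1) * cfg$frame_interval_s

  withr::with_seed(cfg$seed, {
    phase <- runif(1, 0, 2 * pi)
    baseline <- cfg$baseline_level + cfg$baseline_drift_amplitude *
      sin(2 * pi * t / cfg$duration_s + phase)

    onsets <- cfg$onset_times_s
    if (is.null(onsets) && cfg$n_transients > 0) {
      lo <- 2; hi <- max(lo, cfg$duration_s - 3)
      for (try in seq_len(200)) {
        onsets <- sort(runif(cfg$n_transients, lo, hi))
        if (cfg$n_transients < 2 ||
            all(diff(onsets) >= cfg$min_onset_gap_s)) break
      }
      # fall back to even spacing if rejection sampling failed
      if (cfg$n_transients >= 2 && any(diff(onsets) < cfg$min_onset_gap_s))
        onsets <- seq(lo, hi, length.out = cfg$n_transients)
    }
    if (cfg$n_transients == 0) onsets <- numeric(0)
    amps <- if (cfg$n_transients > 0)
      runif(cfg$n_transients, cfg$transient_amplitude_range[1],
            cfg$transient_amplitude_range[2]) else numeric(0)

    signal <- numeric(n)
    for (j in seq_along(onsets))
      signal <- signal + amps[j] *
        transient_kernel(t - onsets[j], cfg$rise_tau_s, cfg$decay_tau_s)

    f <- baseline * (1 + signal)
    if (cfg$noise_sd > 0) f <- f + rnorm(n, 0, cfg$noise_sd)
  })

  list(trace = calcium_trace(t, f, cfg$frame_interval_s),
       truth = list(onset_times_s = onsets,
                    peak_amplitudes_dff = amps,
                    true_baseline = baseline))
}
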